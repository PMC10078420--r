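# lltherm

Interleaved Look-Locker T1 mapping with variable signal averaging, and
T1-based temperature mapping, for low-field (0.1 T) quantitative MRI.

## The problem

MR thermometry by proton resonance frequency shift needs a strong static
field and fails in adipose tissue. At 0.1 T the longitudinal relaxation
time T1 is short, strongly temperature-dependent and nearly linear in
temperature over the mild-hyperthermia range — but mapping it quickly
enough, at workable SNR, requires a carefully engineered acquisition.
`lltherm` implements that chain for people developing or validating
low-field relaxometry and thermometry methods:

* **Signal model** — a saturation pulse nulls the magnetization; a train of
  small pulses (flip angle α, spacing TRα) samples the recovery, whose
  apparent rate obeys `1/T1* = 1/T1 − ln(cos α)/TRα`, bounded by
  `T1*max = −TRα/ln(cos α)`. The sampled signal follows
  `S(t) = A (1 − exp(−t/T1*))`, and T1 is recovered from T1* with a
  pixel-wise flip-angle (B1) map. A steady-state recursion simulator also
  covers imperfect saturation pulses, where no closed form exists.
* **Variable averaging** — repeats of the acquisition truncate their
  repetition time and resample only the early recovery, so the
  per-time-point number of averages NA(k) is front-loaded where the signal
  is weakest; SNR scales as √NA(k). Schedules are built from printed
  constraints (plateaus plus an exact total budget).
* **Synthetic k-space** — digital vial phantoms with temperature-dependent
  T1, smooth B1 fields, Gaussian-weighted phase-encode undersampling and
  complex Gaussian noise (Rician magnitudes).
* **Reconstruction** — Hamming apodization, zero-filling, NA
  normalization, per-repeat background subtraction, region-growing
  segmentation, bounded pixel-wise two-parameter fitting, B1-corrected
  conversion to T1.
* **Thermometry** — per-sample linear laws `T1,i = k_i T + c_i`, the global
  sensitivity `k = K·T1a`, and pixel-wise conversion
  `Tb − Ta = (T1b/T1a − 1)/K`, plus the validation statistics
  (accuracy/precision, Bland-Altman, Grubbs, Levene, ANCOVA-style slope
  comparison, Pearson r²).

A reference dataset from a 15-sample MnCl2-doped water phantom
characterized at 0.1 T is bundled (calibration lines, per-sample T1
estimates under both averaging schemes, heated-series T1 and temperature
tables) and drives the worked examples and validation checks.

## Worked example

Build the protocol, simulate a heated five-vial phantom at two
temperatures, reconstruct T1 maps and convert them to temperature:

```r
library(lltherm)

sq  <- sequence_params(alpha_nominal = 5, TR_alpha = 25, TR_max = 2000, n_slices = 3)
sch <- build_schedule(n_points_max = 79, budget = 948,
                      head_points = 5, head_na = 42, tail_points = 20, tail_na = 3)
n_sampling_points(sq)                 # 79 readout points per repetition
na_profile(sch)[1:8]                  # 42 42 42 42 42 40 37 34
sum(na_profile(sch))                  # 948 averages in total
scan_duration(sch, n_lines = 24, sq)  # 594 s (~10 min)

calib <- sensitivity_calibration()    # bundled linear T1(T) laws
geom  <- vial_geometry(n_vials = 5, grid = c(64, 35))
ph_a  <- make_vial_phantom(geometry = geom, temperature = 24.3, calibration = calib)
ph_b  <- make_vial_phantom(geometry = geom, temperature = 41.7, calibration = calib)
b1    <- make_flip_angle_map(c(64, 35), mean = 4.8, sd = 0.6, seed = 1)
mask  <- gaussian_line_mask(35, 24, seed = 2)     # 24 of 35 lines

t1map <- function(ph, seed) {
  ks  <- simulate_acquisition(ph, b1, sch, sq, mask, noise_sd = 0.05, seed = seed)
  ser <- reconstruct_series(ks, apodize = TRUE)
  t1_map(fit_t1star(ser, sq, mask = ph$labels > 1), b1)
}
tm_a <- t1map(ph_a, 10)
tm_b <- t1map(ph_b, 11)

fit_K(calib)$K                        # 0.0283 per degC (r2 = 0.997)
temp <- temperature_map(tm_b, tm_a, Ta = 24.3, model = 0.0265)
```

Per-vial summaries of `temp` against the simulated truth of 41.7 °C:

```
vial 1: T1    51 ->    73 ms, temperature 38.7 +/- 1.7 degC
vial 2: T1    99 ->   143 ms, temperature 38.1 +/- 1.9 degC
vial 3: T1   138 ->   202 ms, temperature 39.8 +/- 2.1 degC
vial 4: T1   200 ->   291 ms, temperature 39.6 +/- 1.7 degC
vial 5: T1   236 ->   347 ms, temperature 39.5 +/- 1.2 degC
```

Each vial's T1 roughly followed its own linear law while the conversion
used one global coefficient, so the maps underestimate by a couple of
degrees — the same systematic behaviour seen with measured data. The
`run_pipeline()` function wraps these stages (plus validation reporting)
behind a YAML configuration and writes NIfTI maps, CSV tables and a JSON
manifest; `inst/cli/lltherm.R` exposes it as a command-line script.

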