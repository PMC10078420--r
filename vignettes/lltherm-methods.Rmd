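---
title: "Interleaved Look-Locker T1 mapping with variable averaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interleaved Look-Locker T1 mapping with variable averaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lltherm)
```

## Why T1-based thermometry at low field

Proton-resonance-frequency-shift thermometry, the clinical standard for MR
temperature monitoring, scales with the static field and becomes impractical
on low-field (~0.1 T) systems. The longitudinal relaxation time T1 is an
attractive substitute there: T1 is shorter and its relative temperature
sensitivity larger at low field, and over the mild-hyperthermia range
(roughly 25-60 °C in aqueous samples) T1 grows almost linearly with
temperature. The obstacles are speed and SNR: a quantitative T1 map must be
acquired in minutes on hardware with intrinsically weak signal. `lltherm`
implements the full chain that addresses this - an interleaved Look-Locker
readout with partial saturation recovery, a variable signal-averaging
scheme, the matching image reconstruction and pixel-wise fitting, and the
linear calibration that converts T1 maps into temperature maps - together
with a synthetic k-space generator so every stage can be verified without a
scanner.

## Signal model

A saturation pulse (nominally 90°) nulls the longitudinal magnetization;
a train of small pulses with flip angle $\alpha$ spaced by $TR_\alpha$ then
samples the recovery. The readout train accelerates the apparent recovery:

$$\frac{1}{T_1^*} = \frac{1}{T_1} - \frac{\ln\cos\alpha}{TR_\alpha},$$

so the observed time constant $T_1^*$ underestimates $T_1$ and is bounded
above by $T_{1,\max}^* = -TR_\alpha/\ln\cos\alpha$ (6557 ms for
$\alpha = 5°$, $TR_\alpha = 25$ ms) no matter how long the true $T_1$ is.
The sampled magnitude signal follows the two-parameter model

$$S(t) = A\,\bigl(1 - e^{-t/T_1^*}\bigr),$$

with the amplitude $A$ absorbing equilibrium magnetization, flip angle and
steady-state factors. Because the amplitude is free in the fit, recovering
$T_1$ only requires $T_1^*$ and pixel-wise knowledge of the actual flip
angle (a B1 map), through the inverse of the relation above. Three design
constants matter: `n_sampling_points()` counts the readout pulses fitting
in one repetition after the saturation train (79 for TR = 2000 ms,
$TR_\alpha$ = 25 ms, 3 slices), and `max_slices()` gives the interleaving
budget $\lfloor TR_\alpha / t_{line} \rfloor$ (3 slices at 25 ms with
8.33-ms line slots).

`simulate_sampled_train()` is deliberately *not* the closed form: it is a
discrete recursion (relax toward $M_0$ between pulses, scale by
$\cos\alpha$ at each readout pulse, scale by $\cos\theta_{sat}$ at each
saturation pulse) iterated over saturation cycles until the pre-saturation
magnetization is stationary to $10^{-12}$ relative. With a perfect 90°
saturation the recursion lands exactly on a curve of the model form whose
rate constant is the closed-form $T_1^*$ - the package's tests verify this
equivalence - while an imperfect saturation leaves a residual starting
magnetization for which no closed form is available. One subtlety is worth
recording: with perfect saturation every repetition restarts from zero, so
the within-train steady-state amplitude is the recursion's asymptote
(numerically close to $M_0 T_1^*/T_1$); the end-of-repetition value
$M_0^{**} = M_0^* (1 - e^{-TR/T_1^*})$ reported by
`steady_state_amplitudes()` describes where the magnetization sits when the
next saturation pulse arrives. Since the pixel-wise fit treats the
amplitude as free, the distinction never affects $T_1^*$ or $T_1$.

Angles are accepted in degrees everywhere, matching how protocols are
written; echo time is carried for bookkeeping but the model is purely
longitudinal (ideal spoiling, no $T_2^*$ weighting of the fitted shape).
All slices share the nominal time grid $t_k = k\,TR_\alpha$ measured from
saturation; the true per-slice offsets are below $TR_\alpha$ and hence below
the model's resolution.

## Variable averaging

At low field each image must be averaged many times. The early recovery -
where the signal is weakest and the curve steepest - benefits most from
averaging, and because a saturation pulse needs no recovery delay, a repeat
acquisition may simply truncate its repetition time and resample only the
early points. A schedule is therefore a list of blocks `(n_points,
n_repeats)`; its per-time-point averaging profile
$NA(k) = \sum_{\text{blocks with } n_{points} > k} n_{repeats}$ is
non-increasing by construction, and averaging raises SNR as
$\sqrt{NA(k)}$ (`snr_profile()`).

`build_schedule()` reconstructs the study's scheme from its defining
constraints: 79 points, $NA = 42$ on the first five, $NA = 3$ on the last
twenty, and a total budget of $948 = 12 \times 79$ averages, the equivalent
of a constant 12-average scheme. The interior profile between the plateaus
is not prescribed anywhere, so the builder fills it with a deterministic
monotone exponential staircase whose continuous rate is solved (by
`uniroot`) to meet the budget exactly, a left-to-right unit patch absorbing
integer rounding. Repeats are ordered longest first, fixed purely for
determinism. Two consequences of a matched budget are easy to miss: the
total readout time of the two schemes is identical (same number of
line-acquisitions), and the variable scheme actually pays a small overhead
in extra saturation trains - 24 750 versus 24 000 ms per line here, both
within the nominal 10-minute protocol.

## What the synthetic generator emulates - and what it does not

`simulate_acquisition()` composes, per pixel: the steady-state sampled
train with the pixel's local flip angle from a smooth random B1 field
(`make_flip_angle_map()`, mean 4.8°, s.d. 0.6°, Gaussian-correlated,
rescaled to the requested moments exactly); a 2-D DFT to centered k-space;
removal of unsampled phase-encode lines (`gaussian_line_mask()`, 24 of 35
lines drawn without replacement with Gaussian weights of s.d.
$n_{lines}/4$ - a configurable default, since the experimental mask width
is not recorded - with the central line always retained so the DC anchor of
the fit is never lost); and independent complex Gaussian noise per line,
repeat and slice. Magnitude images therefore carry Rician noise with a
noise floor that does *not* average away (magnitude is taken per repeat
before averaging), exactly the regime the reconstruction has to cope with.
No Rician bias correction is applied anywhere.

The generator does **not** model slice excitation profiles, incidental
magnetization transfer between interleaved slices, off-resonance, coil
sensitivity, gradient nonlinearity, or scanner drift over the 10-minute
scan. Passing end-to-end tests therefore demonstrates that the
*reconstruction and conversion chain* is unbiased under ideal acquisition
physics plus realistic sampling and noise - not that a physical scanner
would achieve the same accuracy. This matters for one empirical finding:
in this idealized simulator, matched-budget variable and constant averaging
deliver statistically indistinguishable mean per-vial accuracy (paired
differences of order $10^{-3}$ across 20 seeds), so the package's
comparison test checks aggregate non-inferiority of the variable scheme at
long T1 rather than a strong separation. The experimentally reported
advantage of variable averaging plausibly involves mechanisms outside the
noise-only model (drift, saturation imperfection interacting with
truncated repeats, spatially varying noise).

The phantom itself is five discs on a ring inside a circular bath
(configurable), mirroring a jar of MnCl2-doped vials; vial T1 values either
come from the bundled linear calibration evaluated at the phantom
temperature or are given literally.

## Reconstruction choices

Per repeat and time point the chain is: optional 2-D Hamming apodization
(applied only when undersampling is in play, trading resolution for noise),
optional zero-filling (64 × 35 to 128 × 69 doubles the display grid without
adding information), inverse DFT, magnitude, optional per-repeat background
subtraction, then averaging with division by $NA(k)$. Choices the original
description leaves open are resolved as explicit switches with these
defaults:

* **Negative clipping** (`clip_negatives = TRUE`): background subtraction
  can push magnitudes below zero; the recovery model is non-negative, so
  negatives are clipped at 0.
* **Fit weighting** (`weight_by_na = FALSE`): unweighted least squares per
  pixel. Inverse-variance weighting by $NA(k)$ is available but is *not*
  the default; with heavy early averaging it down-weights the late samples
  that carry most of the long-T1 information.
* **Segmentation**: 4-connected region growing from one seed per vial,
  accepting a neighbour while its intensity stays within
  `tolerance * seed` of the running region mean; seeds below a global
  threshold (image mean by default) are rejected, and a seed landing in an
  existing region merges with it unless told otherwise.

The pixel-wise fit profiles the amplitude out (for fixed $T_1^*$ the
amplitude is linear and closed-form), scans 40 log-spaced candidates for
$T_1^*$ between a tenth of the first sample time and the bound
$T_{1,\max}^*$, and refines the best bracket with `optimize` to $10^{-10}$;
the procedure is deterministic, derivative-free and immune to the local
minima a poor nonlinear start can produce. Degenerate inputs degrade
gracefully: an all-zero pixel is flagged invalid (not an error), a constant
positive signal is fitted exactly by $T_1^* \to 0$ (recovery already
complete), and a signal still rising linearly at the last sample drives
$T_1^*$ into the bound, where the pixel is flagged. 95% confidence
intervals come from the linearized covariance at the optimum. The
conversion to T1 then uses the pixel's actual flip angle; pixels whose
$T_1^*$ meets the *local* bound $T_{1,\max}^*(\alpha_{px})$ are flagged
rather than mapped to a negative T1. A useful robustness figure falls out
of the algebra: a ±7% error in the flip-angle map changes the
reconstructed T1 by less than 1% over the 51-235 ms range (worst case
0.48%), because the correction term is quadratic in $\alpha$ and small
against $1/T_1$ there.

An imperfect saturation pulse is far more damaging: re-simulating the
steady-state train with an 80° saturation pulse and fitting with the
perfect-saturation model biases T1 by 17.0% at T1 = 51 ms and 38.8% at
T1 = 1005 ms (the unweighted fit over 79 points; these are the package's
recomputed values for the published 16%-to-40% range).

## Temperature calibration and mapping

Over the mild-hyperthermia range each sample obeys a linear law
$T_{1,i} = k_i T + c_i$ (`fit_temperature_line()`, ordinary least squares).
The fifteen bundled samples show the per-sample sensitivities themselves
proportional to the sample's reference T1, $k = K\,T_{1a}$, which licenses
a tissue-independent conversion from a pair of T1 maps:

$$T_b - T_a = \frac{1}{K}\left(\frac{T_{1b}}{T_{1a}} - 1\right),$$

algebraically identical to the per-sample form
$T_b - T_a = (T_{1b} - T_{1a})/k_i$ when $k_i = K T_{1a}$ (the package
tests this identity to machine precision). `fit_K()` defaults to unweighted
through-origin least squares - the proportional law has no intercept - and
offers an inverse-variance weighted variant because the regression
convention behind published summary values of K is typically not recorded:
on the bundled table the unweighted fit gives 0.0283 °C⁻¹, the weighted fit
0.0271 °C⁻¹, bracketing the published 0.0265 ± 0.0007 °C⁻¹ from above.
Downstream temperature maps in this package therefore accept K explicitly,
and the worked conversion of the hottest point of the highest-T1 heated
sample (T1 203 → 297 ms from the bundled tables, K = 0.0265, reference
24.3 °C) lands at 41.77 °C against the published 41.7 °C. The critical
practical constraint is that the reference map must be acquired at the same
temperature used when establishing K; mixing references silently biases
every pixel by virtue of the small K.

Validation statistics mirror the study's toolkit: per-sample accuracy
(mean estimate over reference, in percent) and precision (within-sample
s.d. over estimate), Bland-Altman agreement with 95% limits
$\text{bias} \pm 1.96\,\text{s.d.}$ and a one-sample t-test for bias,
a single-outlier two-sided Grubbs test (applied once, not iterated),
Levene's test (mean-centered by default, median-centered optional) gating
an equal-slopes/equal-intercepts nested-F test that decides whether
heating- and cooling-phase calibration data may be pooled, and Pearson
$r^2$ for linearity.

## Problem sizes, tolerances and reproducibility

The test-suite simulations run on a 32 × 21 grid with 2-pixel vial radii -
small enough that the full 948-average schedule simulates in about a
third of a second - while all closed-form checks use the full 79-point,
64 × 35 protocol constants. Monte-Carlo checks use fixed seeds: 1000
pixels for the Rician fit-recovery check (median within 5% at SNR 20),
500 replicates for the spectroscopic-fit noise check, 20 paired seeds for
the schedule comparison at a single-average noise level of 15% of the peak
signal, chosen once to land the synthetic accuracy in the published ~85%
regime. Every random operation takes an explicit seed and restores the
caller's RNG state; identical configurations produce bit-identical k-space
series and identical pipeline manifests. On disk, maps travel as float32
NIfTI, tables and schedules as CSV, configurations as YAML, and simulated
k-space series as RDS containers; `run_pipeline()` writes a JSON manifest
recording the configuration hash, seed and package version of each run.

## Known limitations

* The acquisition model is longitudinal-only; effects that differentiate
  the two averaging schemes in practice (drift, slice profiles,
  magnetization transfer) are out of scope, and the schedule comparison
  should be read accordingly.
* The interior of the averaging profile between the two published plateaus
  is a reconstruction, not the experimental table, which is not available;
  every aggregate constraint (plateaus, budget, monotonicity) is honoured
  exactly.
* Above the mild-hyperthermia range the linear T1 laws fail (protein
  denaturation in tissue); the calibration refuses nothing there beyond a
  range warning, so the user must respect the 20-65 °C validity window.
* Rician bias is simulated but never corrected, matching the reference
  processing chain; at very low SNR the background-subtraction-plus-
  clipping default visibly biases vial means upward.
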