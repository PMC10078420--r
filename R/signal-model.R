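# Closed-form Look-Locker partial-saturation-recovery signal model and its
# inversions, plus a recursion-based sampled-train simulator that supports
# imperfect saturation pulses.

#' Sequence parameter set for the interleaved Look-Locker acquisition
#'
#' Bundles the timing and flip-angle constants of the interleaved
#' partial-saturation-recovery FLASH readout. All angles are in degrees and
#' all times in milliseconds.
#'
#' @param alpha_nominal Nominal readout flip angle (degrees), `0 < alpha < 90`.
#' @param TR_alpha Interval between consecutive readout pulses of the same
#'   slice (ms). One k-space line of every slice is read per `TR_alpha`.
#' @param TE Echo time (ms). Retained for timing bookkeeping only; the signal
#'   model is purely longitudinal.
#' @param TR_max Longest repetition time, i.e. the full saturation-to-
#'   saturation cycle of an untruncated acquisition (ms).
#' @param n_slices Number of interleaved slices.
#' @param t_sat Time slot used to saturate a single slice (ms). Defaults to
#'   `TR_alpha / n_slices` so that the saturation train of all slices fills
#'   exactly one readout interval.
#' @param t_line Time needed to excite and read one k-space line of one
#'   slice (ms). Defaults to `TR_alpha / n_slices`.
#' @param sat_angle Saturation flip angle (degrees). 90 is a perfect
#'   saturation; other values model a miscalibrated saturation pulse.
#'
#' @return An object of class `sequence_params`.
#' @seealso [max_slices()], [n_sampling_points()], [simulate_sampled_train()]
#' @export
sequence_params <- function(alpha_nominal = 5, TR_alpha = 25, TE = 4,
                            TR_max = 2000, n_slices = 3,
                            t_sat = TR_alpha / n_slices,
                            t_line = TR_alpha / n_slices,
                            sat_angle = 90) {
  stopifnot(is.numeric(alpha_nominal), length(alpha_nominal) == 1L,
            is.finite(alpha_nominal), alpha_nominal > 0, alpha_nominal < 90,
            is.numeric(TR_alpha), TR_alpha > 0, is.finite(TR_alpha),
            is.numeric(TE), TE >= 0,
            is.numeric(TR_max), TR_max >= TR_alpha,
            is.numeric(n_slices), n_slices >= 1,
            is.numeric(t_sat), t_sat > 0,
            is.numeric(t_line), t_line > 0,
            is.numeric(sat_angle), sat_angle > 0, sat_angle <= 180)
  n_slices <- as.integer(n_slices)
  if (n_slices > max_slices(TR_alpha, t_line))
    stop("n_slices exceeds the slice budget floor(TR_alpha / t_line)")
  structure(list(alpha_nominal = alpha_nominal, TR_alpha = TR_alpha, TE = TE,
                 TR_max = TR_max, n_slices = n_slices, t_sat = t_sat,
                 t_line = t_line, sat_angle = sat_angle),
            class = "sequence_params")
}

#' Tissue (vial) parameter set
#'
#' @param T1 Longitudinal relaxation time (ms), positive.
#' @param M0 Equilibrium magnetization (arbitrary units), non-negative.
#'
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(T1, M0 = 1) {
  stopifnot(is.numeric(T1), length(T1) == 1L, is.finite(T1), T1 > 0,
            is.numeric(M0), length(M0) == 1L, is.finite(M0), M0 >= 0)
  structure(list(T1 = T1, M0 = M0), class = "tissue_params")
}

deg2rad <- function(x) x * pi / 180

.check_angle <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 90))
    stop("flip angle must lie strictly between 0 and 90 degrees")
}

#' Upper bound of the apparent relaxation time
#'
#' The apparent relaxation time observed under a Look-Locker readout train,
#' `1/T1* = 1/T1 - log(cos(alpha))/TR_alpha`, stays below
#' `-TR_alpha / log(cos(alpha))` for any finite T1. This bound is used as a
#' box constraint in the pixel-wise fit, since values at or above it would
#' imply a negative or infinite T1.
#'
#' @param alpha Actual flip angle (degrees); may be a vector (e.g. a flip
#'   angle map).
#' @param TR_alpha Readout pulse interval (ms).
#'
#' @return Maximum attainable T1* (ms), same shape as `alpha`.
#' @export
t1star_max <- function(alpha, TR_alpha) {
  .check_angle(alpha)
  stopifnot(is.numeric(TR_alpha), all(TR_alpha > 0))
  -TR_alpha / log(cos(deg2rad(alpha)))
}

#' Apparent relaxation time of the Look-Locker readout train
#'
#' Converts a true T1 into the apparent T1* measured under a train of
#' small-flip-angle pulses spaced by `TR_alpha`:
#' `1/T1* = 1/T1 - log(cos(alpha))/TR_alpha`.
#'
#' @param T1 True longitudinal relaxation time (ms); vectorized.
#' @param alpha Flip angle (degrees); scalar or same shape as `T1`.
#' @param TR_alpha Readout pulse interval (ms).
#'
#' @return Apparent relaxation time T1* (ms), always below both `T1` and
#'   [t1star_max()].
#' @export
apparent_t1 <- function(T1, alpha, TR_alpha) {
  if (any(!is.finite(T1)) || any(T1 <= 0)) stop("T1 must be finite and positive")
  .check_angle(alpha)
  stopifnot(all(TR_alpha > 0))
  1 / (1 / T1 - log(cos(deg2rad(alpha))) / TR_alpha)
}

#' Recover the true T1 from an apparent T1*
#'
#' Algebraic inverse of [apparent_t1()]. Requires pixel-wise knowledge of the
#' actual flip angle; values of `T1_star` at or above [t1star_max()] are
#' non-physical (the relation's denominator crosses zero) and raise an error.
#'
#' @param T1_star Apparent relaxation time (ms); vectorized.
#' @param alpha_actual Actual flip angle (degrees); scalar or same shape.
#' @param TR_alpha Readout pulse interval (ms).
#'
#' @return True T1 (ms).
#' @export
true_t1 <- function(T1_star, alpha_actual, TR_alpha) {
  if (any(!is.finite(T1_star)) || any(T1_star <= 0))
    stop("T1_star must be finite and positive")
  .check_angle(alpha_actual)
  bound <- t1star_max(alpha_actual, TR_alpha)
  if (any(T1_star >= bound))
    stop("T1_star at or above t1star_max implies a non-physical (negative) T1")
  1 / (1 / T1_star + log(cos(deg2rad(alpha_actual))) / TR_alpha)
}

#' Steady-state amplitudes of the partial-saturation-recovery train
#'
#' Computes the apparent relaxation time `T1*`, the continuous-readout
#' asymptote `M0* = M0 T1*/T1`, and the per-repetition steady-state amplitude
#' `M0** = M0* (1 - exp(-TR/T1*))`, the value assumed by the longitudinal
#' magnetization at the end of each repetition.
#'
#' The `M0*` relation assumes the readout interval is short compared with the
#' apparent relaxation time; a warning is issued when `TR_alpha > T1*/5`.
#'
#' @param tissue A [tissue_params()] object.
#' @param seq A [sequence_params()] object.
#'
#' @return An object of class `apparent_recovery` with fields `T1_star`,
#'   `M0_star` and `M0_dstar`.
#' @export
steady_state_amplitudes <- function(tissue, seq) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(seq, "sequence_params"))
  T1s <- apparent_t1(tissue$T1, seq$alpha_nominal, seq$TR_alpha)
  if (seq$TR_alpha > T1s / 5)
    warning("TR_alpha is not small compared with T1*; M0* relation is approximate")
  M0s <- tissue$M0 * T1s / tissue$T1
  M0d <- M0s * (1 - exp(-seq$TR_max / T1s))
  structure(list(T1_star = T1s, M0_star = M0s, M0_dstar = M0d),
            class = "apparent_recovery")
}

#' Saturation-recovery curve of the apparent magnetization
#'
#' Longitudinal magnetization at time `t` after a perfect saturation pulse,
#' `Mz(t) = M0** (1 - exp(-t/T1*))`, the two-parameter model fitted
#' pixel-wise during reconstruction.
#'
#' @param t Time since saturation (ms), non-negative; vectorized.
#' @param rec An `apparent_recovery` object from [steady_state_amplitudes()].
#'
#' @return Magnetization values, in `[0, M0_dstar]`.
#' @export
recovery_curve <- function(t, rec) {
  stopifnot(inherits(rec, "apparent_recovery"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and non-negative")
  rec$M0_dstar * (1 - exp(-t / rec$T1_star))
}

#' Maximum number of interleaved slices
#'
#' Floor of `TR_alpha / t_line`: how many slices can each have one line read
#' within one readout interval. A small tolerance absorbs floating-point
#' representation of rational slot lengths such as 25/3.
#'
#' @param TR_alpha Readout pulse interval (ms).
#' @param t_line Per-slice line-readout slot (ms).
#'
#' @return Integer slice count; 0 with a warning when `t_line > TR_alpha`.
#' @export
max_slices <- function(TR_alpha, t_line) {
  stopifnot(TR_alpha > 0, t_line > 0)
  if (t_line > TR_alpha * (1 + 1e-9)) {
    warning("t_line exceeds TR_alpha: no slice fits in one readout interval")
    return(0L)
  }
  as.integer(floor(TR_alpha / t_line + 1e-9))
}

#' Number of sampling time points per repetition
#'
#' After the saturation train (`n_slices * t_sat`, one readout slot when
#' `t_sat = TR_alpha/n_slices`), readout pulses at multiples of `TR_alpha`
#' fill the rest of the repetition time: `floor((TR_max - n_slices*t_sat) /
#' TR_alpha)`. With `TR_max = 2000` ms, `TR_alpha = 25` ms and three slices
#' this yields 79 points.
#'
#' @param seq A [sequence_params()] object, or `TR_max` given explicitly via
#'   the remaining arguments.
#' @param TR_max,TR_alpha,n_slices,t_sat Scalars used when `seq` is `NULL`.
#'
#' @return Integer number of sampling points.
#' @export
n_sampling_points <- function(seq = NULL, TR_max = NULL, TR_alpha = NULL,
                              n_slices = NULL, t_sat = NULL) {
  if (!is.null(seq)) {
    stopifnot(inherits(seq, "sequence_params"))
    TR_max <- seq$TR_max; TR_alpha <- seq$TR_alpha
    n_slices <- seq$n_slices; t_sat <- seq$t_sat
  }
  stopifnot(TR_max > 0, TR_alpha > 0, n_slices >= 1, t_sat > 0)
  as.integer(floor((TR_max - n_slices * t_sat) / TR_alpha + 1e-9))
}

#' Sampling time grid of the readout train
#'
#' All slices share the nominal grid `t_k = k * TR_alpha`, `k = 1..n_points`,
#' measured from the saturation pulse; the sub-`TR_alpha` per-slice offsets
#' are below the model's time resolution.
#'
#' @param seq A [sequence_params()] object.
#' @param n_points Number of sampled time points.
#'
#' @return Numeric vector of times (ms).
#' @export
sampling_times <- function(seq, n_points) {
  stopifnot(inherits(seq, "sequence_params"), n_points >= 1)
  seq$TR_alpha * seq_len(n_points)
}

# Steady-state sampled-train recursion, vectorized over pixels.
# Returns magnetization just before each readout pulse, an n_pixel x n_points
# matrix. Between pulses Mz relaxes toward M0; each readout pulse scales Mz
# by cos(alpha); the saturation pulse scales Mz by cos(sat_angle). Cycles are
# iterated until the pre-saturation magnetization is stationary, so the
# result does not depend on the initial state.
ll_train_mz <- function(T1, alpha, M0, seqp, n_points,
                        n_cycles = 100L, tol = 1e-12) {
  T1 <- as.numeric(T1); alpha <- as.numeric(alpha); M0 <- as.numeric(M0)
  np <- max(length(T1), length(alpha), length(M0))
  T1 <- rep_len(T1, np); alpha <- rep_len(alpha, np); M0 <- rep_len(M0, np)
  E <- exp(-seqp$TR_alpha / T1)
  ca <- cos(deg2rad(alpha))
  cs <- cos(deg2rad(seqp$sat_angle))
  t_train <- seqp$n_slices * seqp$t_sat + n_points * seqp$TR_alpha
  if (t_train > seqp$TR_max * (1 + 1e-9))
    stop("sampling train (saturation slots + n_points * TR_alpha) exceeds TR_max")
  # relaxation from the last readout pulse to the next saturation pulse
  Es <- exp(-(seqp$TR_max - n_points * seqp$TR_alpha) / T1)
  m <- matrix(0, np, n_points)
  z <- rep(0, np)                      # magnetization just before saturation
  for (cyc in seq_len(n_cycles)) {
    cur <- cs * z
    for (k in seq_len(n_points)) {
      cur <- M0 + (cur - M0) * E       # relax one TR_alpha
      m[, k] <- cur                    # just before the readout pulse
      cur <- ca * cur                  # readout pulse
    }
    z_new <- M0 + (cur - M0) * Es
    if (max(abs(z_new - z)) <= tol * max(M0, 1e-300)) { z <- z_new; break }
    z <- z_new
  }
  m
}

#' Simulate the steady-state sampled signal train
#'
#' Discrete Bloch-like recursion for the interleaved partial-saturation-
#' recovery readout: between pulses the longitudinal magnetization relaxes
#' toward `M0`; each readout pulse tips it by `alpha` (leaving a factor
#' `cos(alpha)` and sampling `sin(alpha) * Mz`); each saturation pulse scales
#' it by `cos(sat_angle)`. Cycles are iterated to steady state, so the output
#' is independent of the starting magnetization. With a perfect 90-degree
#' saturation the sampled train lies exactly on a curve of the form
#' `A (1 - exp(-t/T1*))` with the apparent T1* of [apparent_t1()]; an
#' imperfect saturation leaves a residual starting magnetization that biases
#' a fit assuming perfect saturation.
#'
#' @param tissue A [tissue_params()] object.
#' @param seq A [sequence_params()] object (its `sat_angle` is honoured).
#' @param n_points Number of sampled time points; defaults to the maximum
#'   fitting in `TR_max`.
#' @param n_cycles Maximum number of saturation cycles iterated; convergence
#'   (pre-saturation magnetization stationary to 1e-12 relative) normally
#'   occurs much earlier.
#'
#' @return A list with `times` (ms), `signal` (transverse amplitude
#'   `sin(alpha) * Mz` just before each pulse), and `mz` (longitudinal
#'   magnetization just before each pulse).
#' @export
simulate_sampled_train <- function(tissue, seq, n_points = NULL,
                                   n_cycles = 100L) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(seq, "sequence_params"))
  if (is.null(n_points)) n_points <- n_sampling_points(seq)
  stopifnot(n_points >= 1)
  m <- ll_train_mz(tissue$T1, seq$alpha_nominal, tissue$M0, seq, n_points,
                   n_cycles = n_cycles)
  list(times = sampling_times(seq, n_points),
       signal = as.numeric(m[1, ]) * sin(deg2rad(seq$alpha_nominal)),
       mz = as.numeric(m[1, ]))
}
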