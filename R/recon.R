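# Reconstruction chain: k-space apodization and zero-filling, inverse
# transform with averaging normalization, background subtraction,
# region-growing vial segmentation, bounded pixel-wise T1* fitting and
# B1-corrected conversion to T1.

#' 2-D Hamming apodization of a centered k-space matrix
#'
#' Multiplies the k-space by a separable 2-D Hamming window centered on the
#' DC component. The window tapers high spatial frequencies, trading spatial
#' resolution for a lower noise level in the reconstructed images.
#'
#' @param kspace Complex matrix in the centered convention (DC at
#'   `floor(n/2)+1`).
#' @return Apodized complex matrix of the same size.
#' @export
hamming_apodize <- function(kspace) {
  stopifnot(is.matrix(kspace))
  hw <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  kspace * outer(hw(nrow(kspace)), hw(ncol(kspace)))
}

#' Zero-fill a centered k-space matrix
#'
#' Centers the input in a larger zero matrix, which interpolates the image
#' domain onto a finer grid (e.g. 64 x 35 to 128 x 69) without adding
#' information.
#'
#' @param kspace Complex matrix in the centered convention.
#' @param out_shape Target size `c(nx, ny)`, elementwise `>=` the input.
#' @return Complex matrix of size `out_shape`.
#' @export
zero_fill <- function(kspace, out_shape) {
  stopifnot(is.matrix(kspace), length(out_shape) == 2,
            all(out_shape >= dim(kspace)))
  if (all(out_shape == dim(kspace))) return(kspace)
  out <- matrix(0i, out_shape[1], out_shape[2])
  ox <- center_index(out_shape[1]) - center_index(nrow(kspace))
  oy <- center_index(out_shape[2]) - center_index(ncol(kspace))
  out[ox + seq_len(nrow(kspace)), oy + seq_len(ncol(kspace))] <- kspace
  out
}

#' Reconstruct a magnitude image series from a k-space series
#'
#' Per repeat and time point: optional Hamming apodization, optional
#' zero-filling, inverse 2-D DFT, magnitude. Magnitude is taken per repeat
#' and the repeats sampling each time point are then averaged (sum divided
#' by `NA(k)`), mirroring averaging performed in postprocessing rather than
#' during acquisition. When a background region is supplied its per-image
#' mean is subtracted from every repeat before averaging, and negative
#' values are clipped at zero by default (magnitude data are non-negative
#' and the recovery model starts at zero).
#'
#' @param ks A `kspace_series` from [simulate_acquisition()].
#' @param out_shape Optional zero-filled output size `c(nx, ny)`.
#' @param apodize Apply [hamming_apodize()] before transforming.
#' @param background_roi Optional logical matrix (output size) marking a
#'   signal-free region used for per-repeat background subtraction.
#' @param clip_negatives Clip negative post-subtraction values at 0.
#' @param slice Which stored slice to reconstruct.
#'
#' @return An object of class `image_series`: `images` (array
#'   `nx x ny x n_points`), `times` (ms), `na` (averages per time point),
#'   `grid`.
#' @export
reconstruct_series <- function(ks, out_shape = NULL, apodize = FALSE,
                               background_roi = NULL, clip_negatives = TRUE,
                               slice = 1L) {
  stopifnot(inherits(ks, "kspace_series"))
  npmax <- ks$schedule$n_points_max
  na <- na_profile(ks$schedule)
  if (any(na == 0)) stop("time point with zero repeats in the schedule")
  oshape <- if (is.null(out_shape)) ks$grid else as.integer(out_shape)
  if (!is.null(background_roi))
    stopifnot(all(dim(background_roi) == oshape))
  acc <- array(0, c(oshape[1], oshape[2], npmax))
  for (rep_ in ks$repeats) {
    for (k in seq_len(rep_$n_points)) {
      m <- rep_$data[, , k, slice]
      if (apodize) m <- hamming_apodize(m)
      if (!is.null(out_shape)) m <- zero_fill(m, oshape)
      img <- Mod(ifft2c(m))
      if (!is.null(background_roi)) {
        img <- img - mean(img[background_roi])
        if (clip_negatives) img[img < 0] <- 0
      }
      acc[, , k] <- acc[, , k] + img
    }
  }
  for (k in seq_len(npmax)) acc[, , k] <- acc[, , k] / na[k]
  structure(list(images = acc, times = ks$times, na = na, grid = oshape),
            class = "image_series")
}

#' Subtract a background offset from an image series
#'
#' Subtracts, at each time point, the mean intensity of the background
#' region from the whole image, anchoring the recovery curves near zero at
#' the earliest samples. Intended for already-averaged series; during
#' reconstruction the same subtraction can be applied per repeat via the
#' `background_roi` argument of [reconstruct_series()].
#'
#' @param series An `image_series`.
#' @param roi Logical matrix (image size) marking the background region.
#' @param clip_negatives Clip negative results at 0.
#' @return The corrected `image_series`.
#' @export
background_subtract <- function(series, roi, clip_negatives = TRUE) {
  stopifnot(inherits(series, "image_series"), is.logical(roi),
            all(dim(roi) == dim(series$images)[1:2]), any(roi))
  for (k in seq_len(dim(series$images)[3])) {
    img <- series$images[, , k] - mean(series$images[, , k][roi])
    if (clip_negatives) img[img < 0] <- 0
    series$images[, , k] <- img
  }
  series
}

#' Intensity-based region growing segmentation of vials
#'
#' Grows a 4-connected region from each seed pixel, accepting a neighbour
#' while its intensity stays within `tolerance * seed intensity` of the
#' running region mean. Seeds falling below the global background threshold
#' raise an error; a seed landing in an already-grown region either merges
#' with it (default) or raises an error.
#'
#' @param image Reference magnitude image (matrix), typically a late
#'   time point where vial signal is strongest.
#' @param seeds Integer matrix with one row per vial and columns `(x, y)`.
#' @param tolerance Relative intensity tolerance in `(0, 1]`.
#' @param threshold Global background threshold; defaults to the image mean.
#' @param merge Merge regions when a seed falls inside an existing one.
#' @return Integer label matrix (0 = unsegmented, `i` = region of seed `i`).
#' @export
segment_vials <- function(image, seeds, tolerance = 0.25, threshold = NULL,
                          merge = TRUE) {
  stopifnot(is.matrix(image), is.matrix(seeds), ncol(seeds) == 2,
            tolerance > 0, tolerance <= 1)
  if (is.null(threshold)) threshold <- mean(image)
  nx <- nrow(image); ny <- ncol(image)
  labels <- matrix(0L, nx, ny)
  for (i in seq_len(nrow(seeds))) {
    sx <- seeds[i, 1]; sy <- seeds[i, 2]
    stopifnot(sx >= 1, sx <= nx, sy >= 1, sy <= ny)
    if (image[sx, sy] < threshold)
      stop(sprintf("seed %d lies in background (below the global threshold)", i))
    if (labels[sx, sy] > 0L) {
      if (!merge)
        stop(sprintf("seed %d falls inside region %d", i, labels[sx, sy]))
      labels[labels == labels[sx, sy]] <- i
      next
    }
    tol_abs <- tolerance * image[sx, sy]
    queue <- matrix(c(sx, sy), 1)
    labels[sx, sy] <- i
    rsum <- image[sx, sy]; rn <- 1L
    head <- 1L
    while (head <= nrow(queue)) {
      p <- queue[head, ]; head <- head + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nx || q[2] < 1 || q[2] > ny) next
        if (labels[q[1], q[2]] != 0L) next
        if (abs(image[q[1], q[2]] - rsum / rn) <= tol_abs &&
            image[q[1], q[2]] >= threshold) {
          labels[q[1], q[2]] <- i
          rsum <- rsum + image[q[1], q[2]]; rn <- rn + 1L
          queue <- rbind(queue, q)
        }
      }
    }
  }
  labels
}

# Profiled two-parameter least squares of y ~ a * (1 - exp(-t/tau)).
# For fixed tau the amplitude is linear and solved in closed form; tau is
# located by a coarse log-spaced grid followed by local refinement, bounded
# above by tau_max. Returns the estimate, a convergence/boundary flag and a
# linearized covariance for confidence intervals.
fit_recovery_profiled <- function(t, y, w = NULL, tau_max,
                                  n_grid = 40L, conf_level = 0.95) {
  n <- length(t)
  if (is.null(w)) w <- rep(1, n)
  if (all(y == 0))
    return(list(a = 0, tau = NA_real_, valid = FALSE, at_bound = FALSE,
                resid_norm = 0, ci = c(NA_real_, NA_real_)))
  sse_of <- function(tau) {
    f <- 1 - exp(-t / tau)
    a <- max(0, sum(w * y * f) / sum(w * f * f))
    sum(w * (y - a * f)^2)
  }
  taus <- exp(seq(log(t[1] / 10), log(tau_max), length.out = n_grid))
  sses <- vapply(taus, sse_of, 0)
  i <- which.min(sses)
  lo <- taus[max(1L, i - 1L)]; hi <- taus[min(n_grid, i + 1L)]
  opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-10)
  tau <- opt$minimum
  f <- 1 - exp(-t / tau)
  a <- max(0, sum(w * y * f) / sum(w * f * f))
  sse <- sum(w * (y - a * f)^2)
  at_bound <- tau >= tau_max * (1 - 1e-6)
  ci <- c(NA_real_, NA_real_)
  if (n > 2 && a > 0) {
    J <- cbind(f, -a * t / tau^2 * exp(-t / tau))
    s2 <- sse / (n - 2)
    XtX <- crossprod(J * sqrt(w))
    cv <- try(solve(XtX) * s2, silent = TRUE)
    if (!inherits(cv, "try-error") && cv[2, 2] >= 0) {
      half <- stats::qt(1 - (1 - conf_level) / 2, n - 2) * sqrt(cv[2, 2])
      ci <- c(tau - half, tau + half)
    }
  }
  list(a = a, tau = tau, valid = !at_bound, at_bound = at_bound,
       resid_norm = sqrt(sse), ci = ci)
}

#' Fit the two-parameter recovery model to a single time series
#'
#' Least-squares fit of `S(t) = A (1 - exp(-t/T1*))` to one sampled
#' recovery, with the apparent relaxation time constrained to
#' `(0, t1star_bound]`. This is the same engine used pixel-wise by
#' [fit_t1star()]; exposed for fitting simulated or region-averaged trains.
#'
#' @param times Sampling times (ms), strictly increasing, length >= 3.
#' @param signals Sampled signal amplitudes.
#' @param weights Optional per-point weights (e.g. a number-of-averages
#'   profile for inverse-variance weighting); `NULL` for unweighted.
#' @param t1star_bound Upper bound for T1* (ms), typically
#'   [t1star_max()] of the nominal angle.
#' @return A list with `amplitude`, `T1_star`, `valid` (FALSE when the fit
#'   lands on the bound), `resid_norm` and `ci` (95% interval for T1*).
#' @export
fit_recovery <- function(times, signals, weights = NULL, t1star_bound) {
  stopifnot(length(times) == length(signals), length(times) >= 3,
            all(diff(times) > 0), t1star_bound > 0)
  ft <- fit_recovery_profiled(times, signals, weights, tau_max = t1star_bound)
  list(amplitude = ft$a, T1_star = ft$tau, valid = ft$valid,
       resid_norm = ft$resid_norm, ci = ft$ci)
}

#' Bounded pixel-wise T1* fit of an image series
#'
#' Fits the two-parameter saturation-recovery model
#' `S(t) = M0** (1 - exp(-t/T1*))` to every pixel's magnitude time course by
#' least squares, with T1* constrained to `(0, t1star_max]` computed from
#' the nominal flip angle (apparent relaxation times at or beyond the bound
#' would imply a non-physical T1). Pixels whose fit lands on the bound, or
#' that carry no signal, are flagged invalid. 95% confidence half-intervals
#' for T1* come from the linearized covariance at the optimum.
#'
#' @param series An `image_series` (>= 3 time points).
#' @param seq A [sequence_params()] object (nominal angle sets the bound).
#' @param mask Optional logical matrix restricting the fit to labelled
#'   pixels (e.g. from [segment_vials()]); unfitted pixels are invalid.
#' @param weight_by_na Weight residuals by the per-time-point number of
#'   averages (inverse-variance weighting of averaged images). Off by
#'   default: unweighted least squares.
#' @param conf_level Confidence level for the per-pixel intervals.
#'
#' @return An object of class `t1star_map`: matrices `t1star`, `m0`,
#'   `valid`, `resid_norm`, `ci_lower`, `ci_upper`, plus `seq`.
#' @export
fit_t1star <- function(series, seq, mask = NULL, weight_by_na = FALSE,
                       conf_level = 0.95) {
  stopifnot(inherits(series, "image_series"), inherits(seq, "sequence_params"))
  d <- dim(series$images)
  if (d[3] < 3) stop("at least 3 time points are required")
  stopifnot(all(diff(series$times) > 0))
  tmax <- t1star_max(seq$alpha_nominal, seq$TR_alpha)
  w <- if (weight_by_na) series$na else NULL
  t1s <- m0 <- rn <- cil <- ciu <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    if (!mask[ix, iy]) next
    y <- series$images[ix, iy, ]
    ft <- fit_recovery_profiled(series$times, y, w, tau_max = tmax,
                                conf_level = conf_level)
    t1s[ix, iy] <- ft$tau; m0[ix, iy] <- ft$a
    rn[ix, iy] <- ft$resid_norm
    cil[ix, iy] <- ft$ci[1]; ciu[ix, iy] <- ft$ci[2]
    valid[ix, iy] <- ft$valid && ft$a > 0
  }
  structure(list(t1star = t1s, m0 = m0, valid = valid, resid_norm = rn,
                 ci_lower = cil, ci_upper = ciu, seq = seq),
            class = "t1star_map")
}

#' Convert a T1* map to a T1 map with a flip-angle map
#'
#' Applies the inverse apparent-relaxation relation pixel by pixel using the
#' local actual flip angle. Pixels whose T1* reaches or exceeds the local
#' bound `t1star_max(alpha_px)` are flagged invalid rather than producing a
#' negative T1.
#'
#' @param t1star A `t1star_map` from [fit_t1star()].
#' @param b1 Flip-angle map (degrees), same grid; a scalar is recycled.
#' @param TR_alpha Readout pulse interval (ms); defaults to the map's
#'   sequence value.
#' @return An object of class `t1_map`: matrices `t1` and `valid`.
#' @export
t1_map <- function(t1star, b1, TR_alpha = NULL) {
  stopifnot(inherits(t1star, "t1star_map"))
  if (is.null(TR_alpha)) TR_alpha <- t1star$seq$TR_alpha
  if (length(b1) == 1) b1 <- matrix(b1, nrow(t1star$t1star), ncol(t1star$t1star))
  stopifnot(all(dim(b1) == dim(t1star$t1star)))
  bound <- t1star_max(b1, TR_alpha)
  ok <- t1star$valid & is.finite(t1star$t1star) &
    t1star$t1star < bound * (1 - 1e-12)
  t1 <- matrix(NA_real_, nrow(b1), ncol(b1))
  t1[ok] <- 1 / (1 / t1star$t1star[ok] + log(cos(deg2rad(b1[ok]))) / TR_alpha)
  structure(list(t1 = t1, valid = ok), class = "t1_map")
}

#' Bilinear resampling of a map onto a larger grid
#'
#' Used to carry a native-resolution flip-angle map onto the zero-filled
#' reconstruction grid.
#'
#' @param x Numeric matrix.
#' @param out_shape Target size `c(nx, ny)`.
#' @return Resampled matrix.
#' @export
resample_map <- function(x, out_shape) {
  nx <- nrow(x); ny <- ncol(x)
  xi <- (seq_len(out_shape[1]) - 0.5) / out_shape[1] * nx + 0.5
  yi <- (seq_len(out_shape[2]) - 0.5) / out_shape[2] * ny + 0.5
  x0 <- pmin(pmax(floor(xi), 1), nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(pmax(floor(yi), 1), ny); y1 <- pmin(y0 + 1, ny)
  fx <- pmin(pmax(xi - x0, 0), 1); fy <- pmin(pmax(yi - y0, 0), 1)
  out <- matrix(0, out_shape[1], out_shape[2])
  for (j in seq_len(out_shape[2])) {
    a <- x[x0, y0[j]] * (1 - fx) + x[x1, y0[j]] * fx
    b <- x[x0, y1[j]] * (1 - fx) + x[x1, y1[j]] * fx
    out[, j] <- a * (1 - fy[j]) + b * fy[j]
  }
  out
}
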