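# Synthetic-data generator: digital vial phantoms with temperature-dependent
# T1, smooth flip-angle fields, Gaussian-weighted phase-encode undersampling
# masks, and multi-average k-space series with complex Gaussian noise.

#' Vial phantom geometry
#'
#' Disc layout mimicking a cylindrical water bath holding a ring of sample
#' vials: `n_vials` discs of radius `vial_radius` equally spaced on a ring
#' of radius `ring_radius` inside a bath disc of radius `bath_radius`. All
#' lengths are in pixels of the native acquisition grid.
#'
#' @param n_vials Number of vials.
#' @param grid Native matrix size `c(n_read, n_lines)`.
#' @param bath_radius Radius of the surrounding water bath (pixels); `NULL`
#'   for no bath.
#' @param ring_radius Radius of the ring on which vial centers sit.
#' @param vial_radius Vial disc radius.
#' @return A list with `center`, `bath_radius` and a data frame `vials`
#'   (`cx`, `cy`, `r`).
#' @export
vial_geometry <- function(n_vials = 5, grid = c(64, 35), bath_radius = 13,
                          ring_radius = 8, vial_radius = 3) {
  cx <- (grid[1] + 1) / 2; cy <- (grid[2] + 1) / 2
  if (n_vials > 0) {
    ang <- 2 * pi * (seq_len(n_vials) - 1) / n_vials - pi / 2
    vials <- data.frame(cx = cx + ring_radius * cos(ang),
                        cy = cy + ring_radius * sin(ang),
                        r = vial_radius)
  } else {
    vials <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  }
  list(center = c(cx, cy), bath_radius = bath_radius, vials = vials)
}

#' Digital vial phantom
#'
#' Builds the label grid and per-label tissue parameters of a digital
#' phantom. Vial T1 values are either given literally through `vial_t1s` or
#' computed from a linear temperature calibration `T1_i = slope_i * T +
#' intercept_i` evaluated at `temperature` (the first `n` rows of the
#' calibration table, one per vial).
#'
#' Labels: 0 = background (no signal), 1 = water bath (when present),
#' 2, 3, ... = vials in geometry order.
#'
#' @param vial_t1s Numeric vector of vial T1 values (ms); ignored when
#'   `calibration` is given.
#' @param geometry A [vial_geometry()] list.
#' @param temperature Phantom temperature in degrees Celsius (required with
#'   `calibration`); values outside the 20-65 calibration range warn.
#' @param calibration A calibration table (see [calibration_table()]) whose
#'   `slope` and `intercept` columns define the per-vial temperature laws.
#' @param grid Native matrix size `c(n_read, n_lines)`.
#' @param bath_t1 T1 of the bath water (ms); `NULL` drops the bath.
#' @param M0 Equilibrium magnetization assigned to every vial and the bath.
#'
#' @return An object of class `digital_phantom`: `labels` (integer matrix),
#'   `params` (data frame `label`, `T1`, `M0`), `temperature`, `grid`.
#' @export
make_vial_phantom <- function(vial_t1s = NULL, geometry = vial_geometry(),
                              temperature = NULL, calibration = NULL,
                              grid = c(64, 35), bath_t1 = 1800, M0 = 1) {
  if (!is.null(calibration)) {
    stopifnot(!is.null(temperature))
    if (temperature < 20 || temperature > 65)
      warning("temperature outside the 20-65 degC calibration range")
    n <- nrow(geometry$vials)
    stopifnot(nrow(calibration) >= n)
    vial_t1s <- calibration$slope[seq_len(n)] * temperature +
      calibration$intercept[seq_len(n)]
  }
  vial_t1s <- as.numeric(vial_t1s)
  stopifnot(length(vial_t1s) == nrow(geometry$vials), all(vial_t1s > 0))
  labels <- matrix(0L, grid[1], grid[2])
  xg <- matrix(seq_len(grid[1]), grid[1], grid[2])
  yg <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  if (!is.null(geometry$bath_radius) && !is.null(bath_t1)) {
    inb <- (xg - geometry$center[1])^2 + (yg - geometry$center[2])^2 <=
      geometry$bath_radius^2
    labels[inb] <- 1L
  }
  v <- geometry$vials
  for (i in seq_len(nrow(v))) {
    ind <- (xg - v$cx[i])^2 + (yg - v$cy[i])^2 <= v$r[i]^2
    if (any(labels[ind] > 1L)) stop("overlapping vials in the geometry")
    labels[ind] <- i + 1L
  }
  params <- data.frame(label = seq_len(nrow(v) + 1L),
                       T1 = c(if (is.null(bath_t1)) NA_real_ else bath_t1,
                              vial_t1s),
                       M0 = M0)
  params <- params[!is.na(params$T1), , drop = FALSE]
  structure(list(labels = labels, params = params,
                 temperature = temperature, grid = as.integer(grid)),
            class = "digital_phantom")
}

# per-pixel T1 / M0 images from the label grid (background: M0 = 0)
phantom_images <- function(phantom) {
  T1 <- matrix(1, phantom$grid[1], phantom$grid[2])
  M0 <- matrix(0, phantom$grid[1], phantom$grid[2])
  for (i in seq_len(nrow(phantom$params))) {
    sel <- phantom$labels == phantom$params$label[i]
    T1[sel] <- phantom$params$T1[i]
    M0[sel] <- phantom$params$M0[i]
  }
  list(T1 = T1, M0 = M0)
}

#' Smooth random flip-angle field
#'
#' Emulates the spatial transmit-field variation of a volume coil: Gaussian
#' white noise is smoothed with an isotropic Gaussian kernel of the given
#' correlation length (circular convolution via FFT) and then rescaled so
#' that the whole-grid empirical mean and standard deviation equal the
#' requested values exactly.
#'
#' @param grid Matrix size `c(nx, ny)`.
#' @param mean Target mean flip angle (degrees).
#' @param sd Target standard deviation (degrees); 0 gives a constant map.
#' @param correlation_length Smoothing kernel standard deviation (pixels).
#' @param seed Optional integer seed; identical seeds give identical maps.
#' @return A numeric matrix of per-pixel flip angles (degrees), all positive.
#' @export
make_flip_angle_map <- function(grid, mean = 4.8, sd = 0.6,
                                correlation_length = 8, seed = NULL) {
  stopifnot(mean > 0, sd >= 0, length(grid) == 2)
  if (sd == 0) return(matrix(mean, grid[1], grid[2]))
  with_seed(seed, {
    w <- matrix(stats::rnorm(prod(grid)), grid[1], grid[2])
    dx <- pmin(0:(grid[1] - 1), grid[1] - 0:(grid[1] - 1))
    dy <- pmin(0:(grid[2] - 1), grid[2] - 0:(grid[2] - 1))
    ker <- exp(-outer(dx^2, dy^2, "+") / (2 * correlation_length^2))
    sm <- Re(stats::fft(stats::fft(w) * stats::fft(ker), inverse = TRUE)) /
      length(w)
    sm <- (sm - base::mean(sm)) / stats::sd(sm)
    fa <- mean + sd * sm
    if (any(fa <= 0)) {
      warning("flip-angle field clipped at a small positive floor")
      fa[fa <= 0] <- 1e-3
    }
    fa
  })
}

#' Gaussian-weighted phase-encode undersampling mask
#'
#' Keeps exactly `n_keep` of `n_lines` phase-encode lines, drawn without
#' replacement with Gaussian weights centered on the central line. The
#' central (DC) line is always retained so the fit's dynamic range is
#' anchored.
#'
#' @param n_lines Total number of phase-encode lines.
#' @param n_keep Number of lines to keep, `1 <= n_keep <= n_lines`.
#' @param width Standard deviation of the Gaussian weighting (lines);
#'   defaults to `n_lines / 4`.
#' @param seed Optional integer seed.
#' @return Logical vector of length `n_lines`, `TRUE` for sampled lines.
#' @export
gaussian_line_mask <- function(n_lines, n_keep, width = n_lines / 4,
                               seed = NULL) {
  stopifnot(n_keep >= 1, n_keep <= n_lines, width > 0)
  ctr <- center_index(n_lines)
  if (n_keep == n_lines) return(rep(TRUE, n_lines))
  with_seed(seed, {
    others <- setdiff(seq_len(n_lines), ctr)
    w <- stats::dnorm(others - ctr, sd = width)
    keep <- c(ctr, sample(others, n_keep - 1L, prob = w))
    mask <- rep(FALSE, n_lines)
    mask[keep] <- TRUE
    mask
  })
}

#' Simulate a multi-average undersampled k-space series
#'
#' Forward model of the interleaved Look-Locker partial-saturation-recovery
#' acquisition on a digital phantom: the steady-state sampled train is
#' evaluated per pixel with its local flip angle (so each repeat block uses
#' its own truncated repetition time), transformed to centered k-space by a
#' 2-D DFT, reduced to the sampled phase-encode lines, and corrupted with
#' independent complex Gaussian noise per line, repeat and slice. Magnitude
#' images reconstructed from such data therefore carry Rician noise; no bias
#' correction is applied anywhere in the package.
#'
#' @param phantom A [make_vial_phantom()] object.
#' @param b1map Flip-angle map (degrees) on the phantom grid, e.g. from
#'   [make_flip_angle_map()]; `NULL` uses the nominal angle everywhere.
#' @param schedule An [averaging_schedule()].
#' @param seq A [sequence_params()] object.
#' @param mask Logical phase-encode line mask (length = number of lines);
#'   `NULL` samples every line.
#' @param noise_sd Standard deviation of the complex Gaussian noise added to
#'   each real/imaginary k-space component.
#' @param seed Optional integer seed; the whole series is reproducible.
#' @param n_slices_sim Number of slices to store (identical signal,
#'   independent noise); defaults to 1 to keep series compact.
#'
#' @return An object of class `kspace_series`: `repeats` (list of
#'   `list(n_points, data)` with `data` a complex array
#'   `nx x ny x n_points x n_slices_sim`), `line_mask`, `times`, `schedule`,
#'   `seq`, `noise_sd`, `seed`, `grid`.
#' @export
simulate_acquisition <- function(phantom, b1map, schedule, seq, mask = NULL,
                                 noise_sd = 0, seed = NULL,
                                 n_slices_sim = 1L) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(schedule, "averaging_schedule"),
            inherits(seq, "sequence_params"))
  nx <- phantom$grid[1]; ny <- phantom$grid[2]
  if (is.null(b1map)) b1map <- matrix(seq$alpha_nominal, nx, ny)
  stopifnot(all(dim(b1map) == phantom$grid))
  if (is.null(mask)) mask <- rep(TRUE, ny)
  stopifnot(length(mask) == ny, is.logical(mask))
  if (abs(schedule$TR_alpha - seq$TR_alpha) > 1e-9)
    stop("schedule and sequence disagree on TR_alpha")
  if (schedule$n_points_max > n_sampling_points(seq))
    stop("schedule samples more time points than fit in TR_max")
  imgs <- phantom_images(phantom)
  sina <- sin(deg2rad(b1map))
  blocks <- schedule$blocks
  # per-block signal cubes (block n_points sets the truncated TR)
  sig_by_np <- list()
  for (np in unique(blocks$n_points)) {
    seq_b <- seq
    seq_b$TR_max <- seq$n_slices * seq$t_sat + np * seq$TR_alpha
    mz <- ll_train_mz(imgs$T1, b1map, imgs$M0, seq_b, np)
    cube <- array(0, c(nx, ny, np))
    for (k in seq_len(np))
      cube[, , k] <- matrix(mz[, k], nx, ny) * sina
    sig_by_np[[as.character(np)]] <- cube
  }
  with_seed(seed, {
    repeats <- list()
    for (b in seq_len(nrow(blocks))) {
      np <- blocks$n_points[b]
      cube <- sig_by_np[[as.character(np)]]
      for (r in seq_len(blocks$n_repeats[b])) {
        data <- array(0i, c(nx, ny, np, n_slices_sim))
        for (s in seq_len(n_slices_sim)) {
          for (k in seq_len(np)) {
            ks <- fft2c(cube[, , k])
            ks[, !mask] <- 0i
            if (noise_sd > 0) {
              nsamp <- nx * sum(mask)
              ks[, mask] <- ks[, mask] +
                complex(real = stats::rnorm(nsamp, sd = noise_sd),
                        imaginary = stats::rnorm(nsamp, sd = noise_sd))
            }
            data[, , k, s] <- ks
          }
        }
        repeats[[length(repeats) + 1L]] <- list(n_points = np, data = data)
      }
    }
    structure(list(repeats = repeats, line_mask = mask,
                   times = sampling_times(seq, schedule$n_points_max),
                   schedule = schedule, seq = seq, noise_sd = noise_sd,
                   seed = seed, grid = c(nx, ny),
                   n_slices = as.integer(n_slices_sim)),
              class = "kspace_series")
  })
}
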