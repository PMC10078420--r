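# Variable-averaging schedules: construction under budget/head/tail
# constraints, per-time-point NA profiles, scan duration and SNR prediction.

#' Variable-averaging schedule
#'
#' A schedule is an ordered set of blocks. Each block is one truncated
#' acquisition -- the first `n_points` time points of the readout train --
#' repeated `n_repeats` times. Because every truncated repeat still samples
#' the *early* part of the recovery, the derived per-time-point number of
#' averages (NA profile, see [na_profile()]) is non-increasing in time.
#'
#' @param blocks A data frame with integer columns `n_points` and
#'   `n_repeats`, one row per block.
#' @param TR_alpha Readout pulse interval (ms).
#' @param n_points_max Number of time points of the full (untruncated)
#'   acquisition. Defaults to the largest `n_points` among the blocks.
#' @param budget Optional declared total number of averages; when given, the
#'   summed NA profile must equal it exactly.
#'
#' @return An object of class `averaging_schedule`.
#' @export
averaging_schedule <- function(blocks, TR_alpha = 25, n_points_max = NULL,
                               budget = NULL) {
  blocks <- as.data.frame(blocks)
  stopifnot(nrow(blocks) >= 1,
            all(c("n_points", "n_repeats") %in% names(blocks)))
  blocks$n_points <- as.integer(blocks$n_points)
  blocks$n_repeats <- as.integer(blocks$n_repeats)
  if (is.null(n_points_max)) n_points_max <- max(blocks$n_points)
  stopifnot(all(blocks$n_points >= 1), all(blocks$n_points <= n_points_max),
            all(blocks$n_repeats >= 1), TR_alpha > 0)
  # longest-TR-first ordering, fixed for determinism
  blocks <- blocks[order(-blocks$n_points), , drop = FALSE]
  rownames(blocks) <- NULL
  sch <- structure(list(blocks = blocks, TR_alpha = TR_alpha,
                        n_points_max = as.integer(n_points_max)),
                   class = "averaging_schedule")
  total <- sum(na_profile(sch))
  if (!is.null(budget) && total != budget)
    stop(sprintf("schedule violates the declared budget: sum NA = %d != %d",
                 total, budget))
  sch
}

#' Constant-averaging schedule
#'
#' Convenience constructor for the standard scheme: one block of the full
#' train repeated `na` times.
#'
#' @param n_points Number of time points.
#' @param na Number of averages.
#' @param TR_alpha Readout pulse interval (ms).
#' @return An `averaging_schedule`.
#' @export
constant_schedule <- function(n_points, na, TR_alpha = 25) {
  averaging_schedule(data.frame(n_points = n_points, n_repeats = na),
                     TR_alpha = TR_alpha, n_points_max = n_points)
}

#' Per-time-point number-of-averages profile
#'
#' `NA(k)` counts how many repeats sample time point `k`: the sum of
#' `n_repeats` over blocks whose truncated train is at least `k` points
#' long. It is non-increasing in `k` by construction.
#'
#' @param schedule An [averaging_schedule()].
#' @return Integer vector of length `n_points_max`.
#' @export
na_profile <- function(schedule) {
  stopifnot(inherits(schedule, "averaging_schedule"))
  b <- schedule$blocks
  if (nrow(b) == 0) stop("empty schedule")
  prof <- integer(schedule$n_points_max)
  for (i in seq_len(nrow(b)))
    prof[seq_len(b$n_points[i])] <- prof[seq_len(b$n_points[i])] + b$n_repeats[i]
  prof
}

# Layered decomposition of a non-increasing NA profile into blocks:
# each distinct NA level contributes a block spanning the points that reach
# that level.
profile_to_blocks <- function(prof) {
  stopifnot(all(diff(prof) <= 0), all(prof >= 0))
  lev <- unique(prof[prof > 0])               # decreasing
  nxt <- c(lev[-1], 0L)
  data.frame(n_points = vapply(lev, function(L) max(which(prof >= L)), 1L),
             n_repeats = as.integer(lev - nxt))
}

#' Build a variable-averaging schedule from printed constraints
#'
#' Constructs the non-increasing NA profile satisfying the head and tail
#' plateaus and the exact total budget, then decomposes it into truncated-
#' repeat blocks (longest first). The interior between the plateaus is
#' filled with a deterministic, monotone exponential staircase whose
#' continuous rate is solved so that the rounded profile meets the budget
#' exactly (a left-to-right unit patch absorbs the rounding remainder).
#'
#' With the default arguments this reproduces the protocol constraints used
#' throughout the package: 79 points, NA = 42 on the first five points,
#' NA = 3 on the last twenty, total budget 948 (the equivalent of a constant
#' scheme with 12 averages).
#'
#' @param n_points_max Number of time points of the full acquisition.
#' @param budget Exact total number of averages, `sum(na_profile(.))`.
#' @param head_points,head_na Length and NA level of the leading plateau
#'   (0/`NULL` to omit).
#' @param tail_points,tail_na Length and NA level of the trailing plateau
#'   (0/`NULL` to omit).
#' @param TR_alpha Readout pulse interval (ms).
#'
#' @return An `averaging_schedule` whose NA profile satisfies every
#'   constraint exactly.
#' @export
build_schedule <- function(n_points_max = 79, budget = 948,
                           head_points = 5, head_na = 42,
                           tail_points = 20, tail_na = 3,
                           TR_alpha = 25) {
  n <- as.integer(n_points_max)
  stopifnot(n >= 1, budget >= 1)
  if (head_points == 0) head_na <- NULL
  if (tail_points == 0) tail_na <- NULL
  if (!is.null(head_na) && !is.null(tail_na) && head_na < tail_na)
    stop("infeasible: head_na < tail_na violates the non-increasing NA profile")
  if (head_points + tail_points > n)
    stop("infeasible: head_points + tail_points exceed n_points_max")
  prof <- rep(NA_integer_, n)
  if (head_points > 0) prof[seq_len(head_points)] <- as.integer(head_na)
  if (tail_points > 0) prof[(n - tail_points + 1):n] <- as.integer(tail_na)
  interior <- which(is.na(prof))
  m <- length(interior)
  B <- budget - sum(prof, na.rm = TRUE)
  hi <- if (!is.null(head_na)) head_na else B
  lo <- if (!is.null(tail_na)) tail_na else 1
  if (m == 0) {
    if (B != 0)
      stop("infeasible: budget does not match the head/tail allocations")
  } else {
    if (B < m * lo)
      stop("infeasible: budget too small for the tail NA level over the interior")
    if (B > m * hi)
      stop("infeasible: budget exceeds the head NA level over the interior")
    if (B == m * lo) {
      v <- rep(as.integer(lo), m)
    } else if (B == m * hi) {
      v <- rep(as.integer(hi), m)
    } else if (is.null(head_na) && is.null(tail_na)) {
      # unconstrained: flat profile, remainder on the earliest points
      base <- B %/% m
      v <- rep(as.integer(base), m)
      r <- B - base * m
      if (r > 0) v[seq_len(r)] <- v[seq_len(r)] + 1L
    } else {
      shape_sum <- function(g)
        sum(lo + (hi - lo) * exp(-g * seq_len(m) / m)) - B
      g <- stats::uniroot(shape_sum, c(1e-8, 60), tol = 1e-10)$root
      v <- as.integer(round(lo + (hi - lo) * exp(-g * seq_len(m) / m)))
      d <- B - sum(v)
      i <- 1L
      while (d != 0L) {
        cap_up <- if (i == 1L) hi else v[i - 1L]
        cap_dn <- if (i == m) lo else v[i + 1L]
        if (d > 0L && v[i] < cap_up) { v[i] <- v[i] + 1L; d <- d - 1L }
        else if (d < 0L && v[i] > cap_dn) { v[i] <- v[i] - 1L; d <- d + 1L }
        i <- if (i == m) 1L else i + 1L
      }
    }
    prof[interior] <- v
  }
  stopifnot(sum(prof) == budget, all(diff(prof) <= 0))
  averaging_schedule(profile_to_blocks(prof), TR_alpha = TR_alpha,
                     n_points_max = n, budget = budget)
}

#' Total scan duration of a schedule
#'
#' Each repeat of a block lasts the saturation train plus its truncated
#' readout train, and the whole schedule is executed once per acquired
#' phase-encode line:
#' `duration = n_lines * sum_blocks n_repeats * (n_slices*t_sat + n_points*TR_alpha)`.
#'
#' @param schedule An [averaging_schedule()].
#' @param n_lines Number of acquired phase-encode lines.
#' @param seq A [sequence_params()] object.
#' @return Duration in seconds.
#' @export
scan_duration <- function(schedule, n_lines, seq) {
  stopifnot(inherits(schedule, "averaging_schedule"),
            inherits(seq, "sequence_params"), n_lines >= 1)
  b <- schedule$blocks
  ms <- sum(b$n_repeats * (seq$n_slices * seq$t_sat +
                             b$n_points * schedule$TR_alpha))
  n_lines * ms / 1000
}

#' Predicted SNR per sampled time point
#'
#' Averaging `NA(k)` independent repeats raises SNR by `sqrt(NA(k))`, so
#' `SNR(k) = Mz(t_k) * sin(alpha) * sqrt(NA(k)) / noise_sd`, with `Mz` the
#' saturation-recovery curve of [recovery_curve()]. Variable averaging
#' front-loads the averages where the recovery signal is intrinsically weak.
#'
#' @param schedule An [averaging_schedule()].
#' @param tissue A [tissue_params()] object.
#' @param seq A [sequence_params()] object.
#' @param noise_sd Noise standard deviation of a single-average magnitude
#'   image (same units as the signal).
#' @return Numeric vector of SNR values, one per time point.
#' @export
snr_profile <- function(schedule, tissue, seq, noise_sd) {
  stopifnot(noise_sd > 0)
  rec <- steady_state_amplitudes(tissue, seq)
  na <- na_profile(schedule)
  t_k <- schedule$TR_alpha * seq_along(na)
  recovery_curve(t_k, rec) * sin(deg2rad(seq$alpha_nominal)) *
    sqrt(na) / noise_sd
}

#' Write / read a schedule as CSV
#'
#' The CSV has columns `block_index`, `n_points`, `n_repeats`; `TR_alpha`
#' and `n_points_max` are stored in a `#`-prefixed header line.
#'
#' @param schedule An [averaging_schedule()].
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the reconstructed `averaging_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "averaging_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR_alpha=%.10g n_points_max=%d",
                     schedule$TR_alpha, schedule$n_points_max), con)
  b <- cbind(block_index = seq_len(nrow(schedule$blocks)), schedule$blocks)
  utils::write.csv(b, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("TR_alpha=([0-9.eE+-]+) n_points_max=([0-9]+)", hdr))[[1]]
  if (length(m) != 3) stop("missing schedule header line")
  b <- utils::read.csv(path, comment.char = "#")
  averaging_schedule(b[, c("n_points", "n_repeats")],
                     TR_alpha = as.numeric(m[2]),
                     n_points_max = as.integer(m[3]))
}
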