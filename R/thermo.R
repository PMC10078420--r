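# Temperature calibration and mapping: spectroscopic saturation-recovery
# fits, linear T1(T) laws, the global sensitivity coefficient K linking a
# sample's temperature sensitivity to its reference T1, and pixel-wise
# temperature-map generation.

#' Calibration table of linear T1-temperature laws
#'
#' One row per sample: the slope (ms/degC) and intercept (ms) of the linear
#' law `T1_i = k_i * T + c_i`, the fit quality, and optionally the sample's
#' reference T1 at the reference temperature.
#'
#' @param sample Sample identifiers.
#' @param slope,slope_err Temperature sensitivities and standard errors
#'   (ms/degC), slopes positive.
#' @param intercept,intercept_err Intercepts and standard errors (ms).
#' @param r2 Squared Pearson correlation of each calibration fit.
#' @param T1a Reference T1 (ms) measured at `Ta` (optional).
#' @param Ta Reference temperature (degC, optional).
#' @return A data frame of class `calibration_table`.
#' @export
calibration_table <- function(sample, slope, slope_err = NA, intercept,
                              intercept_err = NA, r2 = NA, T1a = NA,
                              Ta = NA) {
  stopifnot(all(slope > 0), all(is.na(r2) | (r2 >= 0 & r2 <= 1)))
  structure(data.frame(sample = sample, slope = slope, slope_err = slope_err,
                       intercept = intercept, intercept_err = intercept_err,
                       r2 = r2, T1a = T1a, Ta = Ta),
            class = c("calibration_table", "data.frame"))
}

#' Read / write a calibration table as CSV
#'
#' @param path File path.
#' @param x A `calibration_table`.
#' @return `read_calibration` returns a `calibration_table`;
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  calibration_table(df$sample, df$slope, df$slope_err, df$intercept,
                    df$intercept_err, df$r2,
                    if ("T1a" %in% names(df)) df$T1a else NA,
                    if ("Ta" %in% names(df)) df$Ta else NA)
}

#' @rdname read_calibration
#' @export
write_calibration <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Two-parameter spectroscopic saturation-recovery fit
#'
#' Fits `Mz(t) = M0 (1 - exp(-t/T1))` to bulk saturation-recovery data by
#' least squares (amplitude profiled out, T1 refined numerically). Supports
#' the logarithmically spaced time grids used for bulk calibration.
#'
#' @param times Sampling times (ms), strictly increasing, length >= 3.
#' @param signals Measured recovery signal at each time.
#' @return A list with `M0`, `T1`, `converged` and `resid_norm`.
#' @export
fit_sr_recovery <- function(times, signals) {
  stopifnot(length(times) == length(signals))
  if (length(times) < 3) stop("at least 3 time points are required")
  stopifnot(all(diff(times) > 0))
  ft <- fit_recovery_profiled(times, signals, w = NULL,
                              tau_max = 100 * max(times))
  if (!ft$valid || !is.finite(ft$tau))
    stop("saturation-recovery fit did not converge")
  list(M0 = ft$a, T1 = ft$tau, converged = ft$valid, resid_norm = ft$resid_norm)
}

#' Linear T1-versus-temperature fit
#'
#' Ordinary least squares of `T1 = k T + c` for one sample, with the squared
#' Pearson correlation as the quality measure.
#'
#' @param temperature Temperatures (degC), length >= 3, non-constant.
#' @param T1 Measured T1 values (ms).
#' @return A list with `slope`, `intercept`, their standard errors, and `r2`.
#' @export
fit_temperature_line <- function(temperature, T1) {
  stopifnot(length(temperature) == length(T1), length(T1) >= 3)
  if (stats::sd(temperature) == 0) stop("degenerate input: constant temperature")
  fit <- stats::lm(T1 ~ temperature)
  cf <- summary(fit)$coefficients
  list(slope = cf["temperature", 1], slope_err = cf["temperature", 2],
       intercept = cf["(Intercept)", 1], intercept_err = cf["(Intercept)", 2],
       r2 = pearson_r2(temperature, T1))
}

#' Fit the global sensitivity coefficient K
#'
#' The per-sample temperature sensitivities follow `k_i = K * T1a_i`, a
#' proportional law through the origin. The default is unweighted
#' through-origin least squares of the slopes on the reference T1 values;
#' an inverse-variance weighted variant (weights `1/slope_err^2`) is
#' available since published summary values may reflect a weighted
#' convention.
#'
#' @param calib A [calibration_table()] with `slope` and `T1a` filled in.
#' @param weighted Use inverse-variance weighting by `slope_err`.
#' @return An object of class `sensitivity_model`: `K` (1/degC), `K_err`,
#'   `r2`, `method`.
#' @export
fit_K <- function(calib, weighted = FALSE) {
  stopifnot(nrow(calib) >= 2, all(is.finite(calib$T1a)))
  w <- if (weighted) 1 / calib$slope_err^2 else NULL
  fit <- stats::lm(slope ~ 0 + T1a, data = calib, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(K = cf["T1a", 1], K_err = cf["T1a", 2],
                 r2 = pearson_r2(calib$T1a, calib$slope),
                 method = if (weighted) "wls_origin" else "ols_origin"),
            class = "sensitivity_model")
}

.as_t1_matrix <- function(x) {
  if (inherits(x, "t1_map")) list(t1 = x$t1, valid = x$valid)
  else list(t1 = x, valid = is.finite(x) & x > 0)
}

#' Pixel-wise temperature map from two T1 maps via the K coefficient
#'
#' Converts the voxel-wise ratio of a T1 map at unknown temperature to the
#' reference map into temperature: `Tb = Ta + (T1b/T1a - 1) / K`. Only the
#' global coefficient K is needed, not the per-sample sensitivities.
#'
#' @param t1_b T1 map (ms) at the unknown temperature (`t1_map` or matrix).
#' @param t1_a Reference T1 map (ms) acquired at `Ta`, same grid.
#' @param Ta Reference temperature (degC).
#' @param model A `sensitivity_model` from [fit_K()], or a positive scalar K.
#' @return An object of class `temperature_map`: `temperature` (degC),
#'   `valid`, `Ta`.
#' @export
temperature_map <- function(t1_b, t1_a, Ta, model) {
  K <- if (inherits(model, "sensitivity_model")) model$K else model
  stopifnot(is.finite(Ta), K > 0)
  b <- .as_t1_matrix(t1_b); a <- .as_t1_matrix(t1_a)
  stopifnot(all(dim(b$t1) == dim(a$t1)))
  ok <- b$valid & a$valid & is.finite(a$t1) & a$t1 > 0
  temp <- matrix(NA_real_, nrow(b$t1), ncol(b$t1))
  temp[ok] <- Ta + (b$t1[ok] / a$t1[ok] - 1) / K
  structure(list(temperature = temp, valid = ok, Ta = Ta),
            class = "temperature_map")
}

#' Temperature map from a known per-sample sensitivity
#'
#' When the sample's own sensitivity `k_i` is known, the temperature change
#' follows the absolute T1 difference: `Tb = Ta + (T1b - T1a) / k_i`. With
#' `k_i = K * T1a` this is algebraically identical to [temperature_map()].
#'
#' @param t1_b,t1_a T1 maps (ms), same grid (`t1_map` objects or matrices).
#' @param Ta Reference temperature (degC).
#' @param k_i Sample temperature sensitivity (ms/degC), positive.
#' @return A `temperature_map`.
#' @export
temperature_from_known_k <- function(t1_b, t1_a, Ta, k_i) {
  stopifnot(is.finite(Ta), k_i > 0)
  b <- .as_t1_matrix(t1_b); a <- .as_t1_matrix(t1_a)
  stopifnot(all(dim(b$t1) == dim(a$t1)))
  ok <- b$valid & a$valid
  temp <- matrix(NA_real_, nrow(b$t1), ncol(b$t1))
  temp[ok] <- Ta + (b$t1[ok] - a$t1[ok]) / k_i
  structure(list(temperature = temp, valid = ok, Ta = Ta),
            class = "temperature_map")
}
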