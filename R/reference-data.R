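# Bundled reference measurements from a 15-sample MnCl2-doped water phantom
# characterized at 0.1 T: spectroscopic T1-temperature calibration lines,
# imaging-based T1 estimates at the reference temperature for both
# averaging schemes, heated-series T1 estimates for the first five samples,
# and the temperatures derived from them. These tables drive the worked
# examples, parts of the validation statistics, and define realistic
# phantom conditions for the simulator.

ref_csv <- function(name)
  utils::read.csv(system.file("extdata", name, package = "lltherm"))

#' Bundled spectroscopic T1-temperature calibration lines
#'
#' Linear law parameters `T1_i = slope_i * T + intercept_i` for 15
#' MnCl2-doped water samples (MnCl2 concentration in micromolar), fitted
#' over nominal 25-60 degC, with standard errors and squared Pearson
#' correlations. Returned as a [calibration_table()]; `T1a` is filled with
#' each sample's calibrated T1 at its measured reference temperature (from
#' [reference_t1_estimates()]) so the table can be fed directly to
#' [fit_K()].
#'
#' @return A `calibration_table` with 15 rows.
#' @export
sensitivity_calibration <- function() {
  df <- ref_csv("sensitivity_calibration.csv")
  ref <- ref_csv("reference_t1_estimates.csv")
  calibration_table(df$sample, df$slope, df$slope_err, df$intercept,
                    df$intercept_err, df$r2,
                    T1a = ref$t1_calibrated[match(df$sample, ref$sample)],
                    Ta = ref$temp_C[match(df$sample, ref$sample)])
}

#' Bundled T1 estimates at the reference temperature
#'
#' Per-sample measured temperature, calibrated (spectroscopic) T1, and the
#' mean T1 estimated by the imaging sequence under the constant (NA = 12)
#' and the variable averaging scheme, with standard deviations. Units: degC
#' and ms.
#'
#' @return A data frame with 15 rows.
#' @export
reference_t1_estimates <- function() ref_csv("reference_t1_estimates.csv")

#' Bundled heated-series T1 estimates (samples S1-S5)
#'
#' Mean estimated T1 and standard deviation for the five low-T1 samples at
#' six measured temperature points (long format).
#'
#' @return A data frame with 30 rows: `sample`, `temp_C`, `temp_err`,
#'   `t1_ms`, `t1_sd`.
#' @export
heated_t1_estimates <- function() ref_csv("heated_t1_estimates.csv")

#' Bundled temperature estimates derived from T1 maps (samples S1-S5)
#'
#' Mean temperature and standard deviation computed from the T1 maps at the
#' five heated points, next to the temperatures measured with a thermal
#' camera (long format).
#'
#' @return A data frame with 25 rows: `sample`, `temp_C`, `temp_err`,
#'   `temp_est_C`, `temp_est_sd`.
#' @export
temperature_estimates <- function() ref_csv("temperature_estimates.csv")
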