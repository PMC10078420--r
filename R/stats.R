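# Evaluation statistics for quantitative maps: accuracy/precision summaries,
# Bland-Altman agreement, Grubbs single-outlier test, Levene's test,
# homogeneity of regression (heating/cooling merge), Pearson r^2.

#' Accuracy and precision of per-sample estimates
#'
#' Accuracy is the mean over samples of `estimate / reference * 100` (in
#' percent); precision is the mean over samples of the within-sample
#' standard deviation normalized by the estimate, `sd / estimate * 100`.
#' Samples (and slices, when rows repeat per slice) enter with equal weight.
#'
#' @param estimates Per-sample mean estimates.
#' @param sds Per-sample standard deviations (optional; `NULL` skips the
#'   precision summary).
#' @param reference Per-sample reference values, positive.
#' @return A list with `accuracy` (%), `accuracy_sd`, `precision` (%),
#'   `precision_sd`, and the per-sample vectors `ratio` and `cv`.
#' @export
accuracy_precision <- function(estimates, sds = NULL, reference) {
  stopifnot(length(estimates) == length(reference), all(reference > 0))
  ratio <- estimates / reference * 100
  out <- list(accuracy = mean(ratio), accuracy_sd = stats::sd(ratio),
              ratio = ratio)
  if (!is.null(sds)) {
    stopifnot(length(sds) == length(estimates))
    cv <- sds / estimates * 100
    out$precision <- mean(cv); out$precision_sd <- stats::sd(cv); out$cv <- cv
  }
  out
}

#' Bland-Altman agreement between two measurement series
#'
#' Differences `a - b` (or `100 * (a - b)/b` in relative mode), their mean
#' (bias) and standard deviation, the 95% limits of agreement
#' `bias +/- 1.96 sd`, and a one-sample t-test for zero bias.
#'
#' @param a,b Paired measurement vectors, equal length >= 2.
#' @param relative Express differences in percent of `b`.
#' @return An object of class `agreement_report`: `bias`, `sd`, `loa_lower`,
#'   `loa_upper`, `p_value`, `differences`, `means`, `relative`.
#' @export
bland_altman <- function(a, b, relative = FALSE) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- if (relative) 100 * (a - b) / b else a - b
  s <- stats::sd(d)
  p <- if (s > 0) stats::t.test(d)$p.value else as.numeric(all(d == 0))
  structure(list(bias = mean(d), sd = s,
                 loa_lower = mean(d) - 1.96 * s,
                 loa_upper = mean(d) + 1.96 * s,
                 p_value = p, differences = d, means = (a + b) / 2,
                 relative = relative),
            class = "agreement_report")
}

#' Grubbs test for a single outlier
#'
#' Two-sided single-outlier Grubbs statistic `G = max|x - mean| / sd`
#' compared against the t-distribution critical value
#' `((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`. Applied once (no iteration), flagging at
#' most one observation.
#'
#' @param values Numeric vector, length >= 3.
#' @param significance Significance level in (0, 1).
#' @return A list with `statistic`, `critical`, `outlier_index` (NA when no
#'   outlier is detected) and `outlier_value`.
#' @export
grubbs_test <- function(values, significance = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 observations")
  stopifnot(significance > 0, significance < 1)
  s <- stats::sd(values)
  if (s == 0)
    return(list(statistic = 0, critical = NA_real_,
                outlier_index = NA_integer_, outlier_value = NA_real_))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - significance / (2 * n), n - 2)
  Gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  idx <- if (G > Gcrit) which.max(dev) else NA_integer_
  list(statistic = G, critical = Gcrit, outlier_index = idx,
       outlier_value = if (is.na(idx)) NA_real_ else values[idx])
}

#' Levene's test for homogeneity of variances
#'
#' Dispersion-of-absolute-deviations ANOVA across groups; the default
#' centers on group means, the Brown-Forsythe variant on medians.
#'
#' @param groups A list of numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"` (Brown-Forsythe).
#' @return A list with `statistic` (F), `df`, and `p_value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  res <- car::leveneTest(y, g, center = if (center == "mean") mean else median)
  list(statistic = res[1, "F value"], df = c(res[1, "Df"], res[2, "Df"]),
       p_value = res[1, "Pr(>F)"])
}

#' Homogeneity-of-regression test for two linear datasets
#'
#' Nested-model F-test comparing a single pooled regression line against
#' separate slopes and intercepts per dataset -- the criterion used to
#' decide whether heating- and cooling-phase calibration data may be merged
#' (merge when `p >= 0.05`).
#'
#' @param x1,y1 First dataset (length >= 3).
#' @param x2,y2 Second dataset (length >= 3).
#' @return A list with `F`, `df`, `p_value`, and `merge` (logical,
#'   `p >= 0.05`).
#' @export
homogeneity_of_regression <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 3, length(x2) >= 3)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("degenerate input: constant predictor")
  x <- c(x1, x2); y <- c(y1, y2)
  g <- factor(rep(1:2, c(length(x1), length(x2))))
  pooled <- stats::lm(y ~ x)
  separate <- stats::lm(y ~ x * g)
  an <- stats::anova(pooled, separate)
  Fv <- an$F[2]; p <- an$`Pr(>F)`[2]
  if (is.na(p)) { Fv <- 0; p <- 1 }   # identical datasets: no extra variance
  list(F = Fv, df = c(an$Df[2], an$Res.Df[2]), p_value = p,
       merge = p >= 0.05)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 2, non-constant.
#' @return r-squared in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)^2
}
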