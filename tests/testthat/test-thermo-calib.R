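# Spectroscopic calibration fits, linear temperature laws, the global
# sensitivity coefficient and temperature-map generation.

test_that("spectroscopic saturation-recovery fit recovers exact data", {
  t <- exp(seq(log(10), log(1500), length.out = 12))
  y <- 1 * (1 - exp(-t / 300))
  ft <- fit_sr_recovery(t, y)
  expect_equal(ft$T1, 300, tolerance = 1e-6)
  expect_equal(ft$M0, 1, tolerance = 1e-6)
  expect_error(fit_sr_recovery(100, 0.5))
})

test_that("saturation-recovery fit tolerates 1% noise on log-spaced grids", {
  T1 <- 300
  t <- exp(seq(log(10), log(5 * T1), length.out = 12))
  clean <- 1 - exp(-t / T1)
  set.seed(77)
  est <- vapply(1:500, function(i)
    fit_sr_recovery(t, clean + rnorm(12, sd = 0.01))$T1, 0)
  expect_lt(abs(stats::median(est) - T1) / T1, 0.03)
})

test_that("temperature-line fit matches the bundled sample laws", {
  T <- seq(25, 60, by = 5)
  exact <- 1.25 * T + 21
  ft <- suppressWarnings(fit_temperature_line(T, exact))
  expect_equal(ft$slope, 1.25, tolerance = 1e-9)
  expect_equal(ft$intercept, 21, tolerance = 1e-9)
  expect_equal(ft$r2, 1, tolerance = 1e-12)
  # the fitted law evaluated at the reference temperature reproduces the
  # bundled calibrated T1 of the first sample (51 +/- 5 ms)
  expect_equal(round(1.25 * 24.3 + 21), 51)
  # parameter recovery from data simulated off the steepest sample's law
  set.seed(5)
  noisy <- 49 * T + 574 + rnorm(length(T), sd = 40)
  ft15 <- fit_temperature_line(T, noisy)
  expect_lt(abs(ft15$slope - 49), 3)     # within the law's printed uncertainty
  expect_error(fit_temperature_line(rep(25, 4), 1:4))
})

test_that("sensitivity coefficient K is recovered from proportional data", {
  tab <- calibration_table(sample = paste0("V", 1:6),
                           slope = 0.02 * c(100, 200, 400, 700, 1000, 1500),
                           intercept = rep(10, 6),
                           T1a = c(100, 200, 400, 700, 1000, 1500))
  expect_equal(suppressWarnings(fit_K(tab)$K), 0.02, tolerance = 1e-12)
  # parameter-recovery simulation at 5% noise: within the printed uncertainty
  set.seed(12)
  t1a <- seq(50, 1760, length.out = 15)
  Ks <- vapply(1:300, function(i) {
    k <- 0.0265 * t1a * (1 + rnorm(15, sd = 0.05))
    fit_K(calibration_table(sample = 1:15, slope = k, intercept = 0,
                            T1a = t1a))$K
  }, 0)
  expect_lt(abs(mean(Ks) - 0.0265), 0.0007)
  expect_lt(abs(mean(Ks) - 0.0265) / 0.0265, 0.01)   # bias under 1%
})

test_that("bundled calibration yields K in the published range", {
  calib <- sensitivity_calibration()
  K_u <- fit_K(calib)
  K_w <- fit_K(calib, weighted = TRUE)
  expect_gt(K_u$r2, 0.99)
  for (K in c(K_u$K, K_w$K)) {
    expect_gt(K, 0.025)
    expect_lt(K, 0.029)
  }
  expect_lt(K_w$K, K_u$K)  # weighting favours the shallow, precise samples
})

test_that("temperature maps follow the ratio law and its algebraic twin", {
  t1a <- matrix(c(203, 100, 150, 250), 2)
  # equal maps: reference temperature everywhere
  tm0 <- temperature_map(t1a, t1a, Ta = 24.3, model = 0.0265)
  expect_true(all(tm0$temperature == 24.3))
  # worked example: S5 between the reference and the hottest point
  tm <- temperature_map(matrix(297), matrix(203), Ta = 24.3, model = 0.0265)
  expect_equal(tm$temperature[1, 1], 24.3 + (297 / 203 - 1) / 0.0265,
               tolerance = 1e-12)
  expect_equal(tm$temperature[1, 1], 41.7, tolerance = 0.1)
  # doubling K halves the temperature change
  tm2 <- temperature_map(matrix(297), matrix(203), Ta = 24.3, model = 0.053)
  expect_equal(tm2$temperature[1, 1] - 24.3, (tm$temperature[1, 1] - 24.3) / 2,
               tolerance = 1e-9)
  # per-sample law: a known T1 difference maps to the exact step
  k_i <- 3.7
  ta <- matrix(150, 2, 2)
  tb <- ta + k_i * 10
  tk <- temperature_from_known_k(tb, ta, Ta = 25, k_i = k_i)
  expect_true(all(abs(tk$temperature - 35) < 1e-12))
  # with k_i = K * T1a the two conversions agree pixel-wise exactly
  K <- 0.0265
  t1b <- t1a * matrix(c(1.2, 1.5, 0.9, 1.05), 2)
  via_K <- temperature_map(t1b, t1a, 24.3, K)
  via_k <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2)
    via_k[i, j] <- temperature_from_known_k(t1b[i, j, drop = FALSE],
                                            t1a[i, j, drop = FALSE],
                                            24.3, K * t1a[i, j])$temperature
  expect_equal(via_K$temperature, via_k, tolerance = 1e-12)
})

test_that("phantoms built on a linear law return their temperature exactly", {
  calib <- sensitivity_calibration()
  geom <- vial_geometry(3, tiny_grid, bath_radius = 9, ring_radius = 5.5,
                        vial_radius = 2)
  ph_a <- make_vial_phantom(geometry = geom, temperature = 24.3,
                            calibration = calib, grid = tiny_grid,
                            bath_t1 = NULL)
  ph_b <- make_vial_phantom(geometry = geom, temperature = 37,
                            calibration = calib, grid = tiny_grid,
                            bath_t1 = NULL)
  for (i in 1:3) {
    t1a <- ph_a$params$T1[i]; t1b <- ph_b$params$T1[i]
    tk <- temperature_from_known_k(matrix(t1b), matrix(t1a), 24.3,
                                   calib$slope[i])
    expect_equal(tk$temperature[1, 1], 37, tolerance = 1e-9)
  }
})

test_that("calibration tables round-trip through CSV", {
  calib <- sensitivity_calibration()
  path <- tempfile(fileext = ".csv")
  write_calibration(calib, path)
  back <- read_calibration(path)
  expect_equal(as.data.frame(back), as.data.frame(calib), tolerance = 1e-12)
})
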