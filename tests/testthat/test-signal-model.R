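# Closed-form apparent-relaxation model, its inversions, and the
# steady-state sampled-train recursion.

test_that("apparent T1 matches high-precision evaluations and limits", {
  # frozen from 40-digit arbitrary-precision evaluation of the defining relation
  expect_equal(apparent_t1(51, 5, 25), 50.60640246011096, tolerance = 1e-12)
  # vanishing flip angle: correction term disappears
  expect_equal(apparent_t1(400, 1e-4, 25), 400, tolerance = 1e-6)
  # infinite-T1 limit equals the T1* bound
  expect_equal(apparent_t1(1e12, 5, 25), t1star_max(5, 25), tolerance = 1e-6)
  expect_error(apparent_t1(-5, 5, 25))
  expect_error(apparent_t1(Inf, 5, 25))
  expect_error(apparent_t1(100, 95, 25))
})

test_that("T1* bound is exact, decreasing in alpha and linear in TR_alpha", {
  expect_equal(t1star_max(5, 25), 6557.273010886369, tolerance = 1e-12)
  expect_lt(t1star_max(10, 25), t1star_max(5, 25))
  expect_equal(t1star_max(5, 50), 2 * t1star_max(5, 25))
  expect_error(t1star_max(0, 25))
  expect_error(t1star_max(90, 25))
})

test_that("apparent/true T1 are mutual inverses over the physiological range", {
  grid_t1 <- c(10, 51, 100, 235, 500, 1005, 1759, 5000)
  grid_alpha <- c(1, 4.8, 5, 10, 20)
  for (T1 in grid_t1) for (a in grid_alpha) {
    ts <- apparent_t1(T1, a, 25)
    expect_lt(ts, min(T1, t1star_max(a, 25)))
    expect_equal(true_t1(ts, a, 25), T1, tolerance = 1e-9)
  }
  expect_equal(true_t1(50.60640246011096, 5, 25), 51, tolerance = 1e-9)
  # pole of the conversion
  expect_error(true_t1(t1star_max(5, 25), 5, 25), "non-physical")
})

test_that("steady-state amplitudes follow the closed-form chain", {
  sq <- tiny_seq()
  rec <- expect_warning(
    steady_state_amplitudes(tissue_params(235), sq), NA)
  # frozen 40-digit values for T1 = 235 ms, alpha = 5 deg, TR_alpha = 25 ms,
  # TR = 2000 ms
  expect_equal(rec$T1_star, 226.86943753416747, tolerance = 1e-12)
  expect_equal(rec$M0_star, 0.9654018618475212, tolerance = 1e-12)
  expect_equal(rec$M0_dstar, 0.9652586025018502, tolerance = 1e-12)
  expect_true(rec$M0_dstar <= rec$M0_star)
  expect_lte(rec$M0_star, 1)
  # near-zero flip angle: asymptote approaches M0
  sq0 <- sequence_params(alpha_nominal = 0.01, TR_alpha = 25, TR_max = 2000,
                         n_slices = 1, t_sat = 25, t_line = 25)
  rec0 <- steady_state_amplitudes(tissue_params(300), sq0)
  expect_equal(rec0$M0_star, 1, tolerance = 1e-5)
  # per-repetition amplitude ratio at TR = 10 T1*
  t1 <- 100
  ts <- apparent_t1(t1, 5, 25)
  sq10 <- sequence_params(TR_max = 10 * ts)
  rec10 <- suppressWarnings(steady_state_amplitudes(tissue_params(t1), sq10))
  expect_equal(rec10$M0_dstar / rec10$M0_star, 1 - exp(-10), tolerance = 1e-12)
  # short T1 versus the readout interval triggers the validity warning
  expect_warning(steady_state_amplitudes(tissue_params(51), sq),
                 "approximate")
})

test_that("recovery curve is anchored at zero and saturates monotonically", {
  rec <- steady_state_amplitudes(tissue_params(300), tiny_seq())
  expect_equal(recovery_curve(0, rec), 0)
  expect_equal(recovery_curve(rec$T1_star, rec),
               rec$M0_dstar * (1 - exp(-1)), tolerance = 1e-12)
  expect_lt(abs(recovery_curve(5 * rec$T1_star, rec) - rec$M0_dstar),
            0.007 * rec$M0_dstar)
  t <- seq(0, 2000, by = 25)
  y <- recovery_curve(t, rec)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= rec$M0_dstar))
  expect_error(recovery_curve(-1, rec))
})

test_that("sampled train with perfect saturation lies on the closed-form curve", {
  sq <- tiny_seq()
  for (T1 in c(51, 100, 1005)) {
    tr <- simulate_sampled_train(tissue_params(T1), sq)
    expect_length(tr$signal, 79)
    ft <- fit_recovery(tr$times, tr$signal, t1star_bound = t1star_max(5, 25))
    # the recursion's rate constant is exactly the apparent T1
    expect_equal(ft$T1_star, apparent_t1(T1, 5, 25), tolerance = 1e-6)
    expect_lt(ft$resid_norm, 1e-6 * max(tr$signal))
  }
})

test_that("imperfect saturation leaves a residual starting magnetization", {
  sq80 <- sequence_params(sat_angle = 80)
  tr <- simulate_sampled_train(tissue_params(51), sq80)
  sq90 <- tiny_seq()
  tr90 <- simulate_sampled_train(tissue_params(51), sq90)
  # extra signal at the earliest samples relative to perfect saturation
  expect_gt(tr$signal[1], tr90$signal[1])
  # steady state: more cycles do not change the train
  tr_a <- simulate_sampled_train(tissue_params(1005), sq80, n_cycles = 10L)
  tr_b <- simulate_sampled_train(tissue_params(1005), sq80, n_cycles = 30L)
  expect_equal(tr_a$signal, tr_b$signal, tolerance = 1e-9)
  # train longer than the repetition time is rejected
  expect_error(simulate_sampled_train(tissue_params(100), sq90,
                                      n_points = 100), "exceeds")
})

test_that("slice budget and sampling-point count reproduce the protocol", {
  expect_identical(max_slices(25, 25 / 3), 3L)
  expect_identical(max_slices(25, 25), 1L)
  expect_identical(max_slices(50, 25 / 3), 6L)
  expect_warning(res <- max_slices(25, 30), "no slice")
  expect_identical(res, 0L)
  expect_identical(n_sampling_points(tiny_seq()), 79L)
  expect_identical(sampling_times(tiny_seq(), 3), c(25, 50, 75))
})
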