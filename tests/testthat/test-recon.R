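# Reconstruction chain: apodization, zero-filling, averaging normalization,
# background subtraction, segmentation, bounded T1* fitting, B1 correction.

test_that("Hamming apodization is symmetric and never adds energy", {
  z <- matrix(0i, 16, 9)
  expect_identical(hamming_apodize(z), z * outer(rep(1, 16), rep(1, 9)))
  set.seed(1)
  ks <- matrix(complex(real = rnorm(15 * 9), imaginary = rnorm(15 * 9)), 15, 9)
  out <- hamming_apodize(ks)
  expect_lte(sum(Mod(out)^2), sum(Mod(ks)^2))
  w <- hamming_apodize(matrix(1 + 0i, 15, 9))
  expect_equal(Re(w), Re(w[15:1, 9:1]), tolerance = 1e-12)
  expect_equal(Re(w[8, 5]), 1, tolerance = 1e-12)   # centre weight for odd dims
})

test_that("zero-filling pads around the centre and preserves peak location", {
  ks <- matrix(complex(real = rnorm(64 * 35)), 64, 35)
  out <- zero_fill(ks, c(128, 69))
  expect_identical(dim(out), c(128L, 69L))
  expect_identical(zero_fill(ks, dim(ks)), ks)
  expect_error(zero_fill(ks, c(32, 35)))
  expect_equal(sum(Mod(out) > 0), sum(Mod(ks) > 0))
  # point source at the native centre stays at the interpolated centre
  img <- matrix(0, 64, 35)
  img[33, 18] <- 1                      # centre pixel of the native grid
  ksp <- lltherm:::fft2c(img)
  up <- Mod(lltherm:::ifft2c(zero_fill(ksp, c(128, 69))))
  peak <- which(up == max(up), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, ]), c(65L, 35L))  # centre of the fine grid
})

test_that("reconstruction averages repeats and normalizes by NA", {
  sq <- tiny_seq()
  ph <- tiny_phantom(c(100, 300))
  ks1 <- simulate_acquisition(ph, NULL, constant_schedule(6, 1), sq, noise_sd = 0)
  ks5 <- simulate_acquisition(ph, NULL, constant_schedule(6, 5), sq, noise_sd = 0)
  s1 <- reconstruct_series(ks1)
  s5 <- reconstruct_series(ks5)
  expect_equal(s1$images, s5$images, tolerance = 1e-12)
  expect_identical(s5$na, rep(5L, 6))
  # explicit mean over noisy repeats
  ksn <- simulate_acquisition(ph, NULL, constant_schedule(3, 4), sq,
                              noise_sd = 0.3, seed = 2)
  ser <- reconstruct_series(ksn)
  manual <- Reduce(`+`, lapply(ksn$repeats, function(r)
    Mod(lltherm:::ifft2c(r$data[, , 2, 1])))) / 4
  expect_equal(ser$images[, , 2], manual, tolerance = 1e-12)
})

test_that("background subtraction removes a constant offset exactly", {
  sq <- tiny_seq()
  ph <- tiny_phantom(100)
  ks <- simulate_acquisition(ph, NULL, constant_schedule(4, 1), sq, noise_sd = 0)
  ser <- reconstruct_series(ks)
  roi <- ph$labels == 0
  # noise-free data with an empty background: unchanged
  sub0 <- background_subtract(ser, roi)
  expect_equal(sub0$images, ser$images, tolerance = 1e-10)
  shifted <- ser
  shifted$images <- shifted$images + 0.37
  fixed <- background_subtract(shifted, roi, clip_negatives = FALSE)
  expect_equal(fixed$images, ser$images, tolerance = 1e-10)
})

test_that("region growing recovers disc vials from seeds", {
  ph <- tiny_phantom(c(100, 100, 100))
  img <- matrix(0.02, tiny_grid[1], tiny_grid[2])
  img[ph$labels > 1] <- 1
  set.seed(4)
  img <- img + matrix(rnorm(prod(tiny_grid), sd = 0.01), tiny_grid[1])
  geom <- vial_geometry(3, tiny_grid, bath_radius = 9, ring_radius = 5.5,
                        vial_radius = 2)
  seeds <- round(as.matrix(geom$vials[, c("cx", "cy")]))
  labs <- segment_vials(img, seeds, tolerance = 0.3)
  for (i in 1:3) {
    truth <- ph$labels == i + 1
    got <- labs == i
    # agreement up to a 1-pixel boundary band
    core <- truth & !boundary_band(truth)
    expect_true(all(got[core]))
    expect_true(all(!got[!truth & !boundary_band(truth)]))
  }
  # vanishing tolerance keeps only the seed
  one <- segment_vials(img, seeds[1, , drop = FALSE], tolerance = 1e-9)
  expect_identical(sum(one == 1), 1L)
  # seeds in the same disc merge by default
  two <- segment_vials(img, rbind(seeds[1, ], seeds[1, ] + c(1, 0)),
                       tolerance = 0.3)
  expect_identical(sum(two == 1), 0L)   # first region relabelled to 2
  expect_gt(sum(two == 2), 1L)
  expect_error(segment_vials(img, matrix(c(1, 1), 1), tolerance = 0.3),
               "background")
})

test_that("pixel-wise T1* fit is exact on noise-free data and bounded", {
  t <- 25 * (1:40)
  truth <- 1 * (1 - exp(-t / 120))
  ser <- series_from_signal(t, lapply(truth, function(v) matrix(v, 2, 2)))
  fit <- fit_t1star(ser, tiny_seq())
  expect_equal(fit$t1star[1, 1], 120, tolerance = 1e-6)
  expect_equal(fit$m0[1, 1], 1, tolerance = 1e-6)
  expect_true(all(fit$valid))
  expect_true(all(fit$ci_lower <= fit$t1star & fit$t1star <= fit$ci_upper))
  # signal still rising linearly at the last sample: T1* driven to the
  # bound and flagged
  ramp <- series_from_signal(t, lapply(t / max(t), function(v) matrix(v, 1, 1)))
  ffit <- fit_t1star(ramp, tiny_seq())
  expect_false(ffit$valid[1, 1])
  # all-zero pixel: invalid, not an error
  zfit <- fit_t1star(series_from_signal(t, lapply(t, function(.) matrix(0, 1, 1))),
                     tiny_seq())
  expect_false(zfit$valid[1, 1])
})

test_that("T1* recovered within 5% under Rician noise at SNR 20", {
  t1s_true <- 200
  t <- 25 * (1:79)
  clean <- 1 - exp(-t / t1s_true)
  n_px <- 1000
  set.seed(42)
  est <- vapply(seq_len(n_px), function(i) {
    noisy <- sqrt((clean + rnorm(79, sd = 1 / 20))^2 + rnorm(79, sd = 1 / 20)^2)
    fit_recovery(t, noisy, t1star_bound = t1star_max(5, 25))$T1_star
  }, 0)
  expect_lt(abs(stats::median(est) - t1s_true) / t1s_true, 0.05)
})

test_that("B1 correction converts T1* to T1 and respects local bounds", {
  t <- 25 * (1:40)
  ts <- apparent_t1(200, 4.8, 25)
  ser <- series_from_signal(t, lapply(1 - exp(-t / ts),
                                      function(v) matrix(v, 2, 2)))
  fit <- fit_t1star(ser, sequence_params(alpha_nominal = 4.8))
  # uniform map at the nominal angle equals the scalar conversion
  tm <- t1_map(fit, 4.8)
  expect_equal(tm$t1[1, 1], 200, tolerance = 1e-6)
  # 7% flip-angle-map error moves T1 by less than 1% over the sample range
  for (T1 in seq(51, 235, by = 8)) {
    ts_i <- apparent_t1(T1, 4.8, 25)
    for (f in c(0.93, 1.07)) {
      t1_wrong <- true_t1(ts_i, 4.8 * f, 25)
      expect_lt(abs(t1_wrong - T1) / T1, 0.01)
    }
  }
  # local bound: pixels whose T1* exceeds t1star_max(alpha_px) are invalid
  fit2 <- fit
  fit2$t1star[1, 1] <- t1star_max(6, 25) + 1
  tm2 <- t1_map(fit2, matrix(6, 2, 2))
  expect_false(tm2$valid[1, 1])
  expect_true(tm2$valid[2, 2])
})

test_that("flip-angle field pipeline recovers vial T1 within 1% noise-free", {
  sq <- tiny_seq()
  ph <- tiny_phantom(c(51, 235))
  b1 <- make_flip_angle_map(tiny_grid, seed = 11)
  ks <- simulate_acquisition(ph, b1, constant_schedule(40, 1), sq, noise_sd = 0)
  ser <- reconstruct_series(ks)
  fit <- fit_t1star(ser, sq, mask = ph$labels > 1)
  tm <- t1_map(fit, b1)
  means <- vial_means(tm$t1, ph)
  expect_equal(means, c(51, 235), tolerance = 0.01)
})
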