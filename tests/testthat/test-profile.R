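test_that("bicubic profile extraction reproduces simple images", {
  img <- matrix(7.5, 32L, 32L)
  prof <- extract_profile(img, rbind(c(2, 2), c(28, 28)), n_samples = 11L)
  expect_equal(prof$intensities, rep(7.5, 11L), tolerance = 1e-9)
  # 4 samples on a 2-px line -> evenly spaced positions
  p4 <- extract_profile(img, rbind(c(5, 5), c(7, 5)), n_samples = 4L)
  expect_equal(p4$positions, seq(0, 2, length.out = 4L))
  expect_error(extract_profile(img, rbind(c(5, 5), c(5, 5))), "zero-length")
  expect_error(extract_profile(img, rbind(c(-3, 5), c(5, 5))), "exits")
})

test_that("profiles across a rendered ridge peak at the ridge position", {
  truth <- contour_series(list(straight_contour(c(4, 20.4), c(44, 20.4),
                                                n = 30L)))
  vid <- render_video(truth, render_config(image_size = c(48L, 48L),
                                           noise = "none"))
  prof <- extract_profile(vid$video[, , 1L], rbind(c(24, 12), c(24, 28)),
                          n_samples = 17L)
  peak_pos <- prof$positions[which.max(prof$intensities)]
  expect_lt(abs((12 + peak_pos) - 20.4), 0.5 + 1e-9)
})

test_that("kriging upsampling interpolates exactly and finds peaks", {
  u <- seq(0, 10, length.out = 9L)
  z <- c(1, 4, 2, 8, 3, 7, 5, 2, 6)
  # a grid containing the raw positions: interpolation is exact there
  up <- krig_upsample(intensity_profile(u, z), n_out = 81L)
  at_nodes <- match(round(u, 9), round(up$positions, 9))
  expect_false(anyNA(at_nodes))
  expect_equal(up$intensities[at_nodes], z, tolerance = 1e-6)
  # identity on matching support size
  up9 <- krig_upsample(intensity_profile(u, z), n_out = 9L)
  expect_equal(up9$intensities, z, tolerance = 1e-6)
  # linear ramp stays a ramp
  ramp <- krig_upsample(intensity_profile(u, 2 * u + 1), n_out = 50L)
  expect_equal(ramp$intensities, 2 * ramp$positions + 1, tolerance = 1e-6)
  # 8-sample noiseless Gaussian: upsampled peak within 0.1 px of centre
  u8 <- seq(0, 14, length.out = 8L)
  g <- krig_upsample(gauss_profile(u8, mu = 6.7, sigma = 2), n_out = 200L)
  expect_lt(abs(g$positions[which.max(g$intensities)] - 6.7), 0.1)
})

test_that("the SNR gate separates signal from noise and is monotone", {
  u <- seq(0, 12, length.out = 100L)
  clean <- gauss_profile(u)
  g1 <- snr_gate(clean, threshold = 5)
  expect_true(g1$pass)
  expect_gt(g1$snr, 100)   # noiseless ridge: near-degenerate noise estimate
  # exactly zero residual noise reports +Inf and passes
  ramp <- intensity_profile(u, 3 * u + 2)
  expect_equal(snr_gate(ramp, threshold = 1)$snr, Inf)
  set.seed(1)
  for (rep in 1:5) {
    noise <- intensity_profile(u, rnorm(100L, 50, 5))
    g <- snr_gate(noise, threshold = 1)
    expect_false(g$pass && g$snr < 1)  # gate consistency
    expect_lt(g$snr, 5)                # pure noise never looks like signal
    # monotonicity: raising the threshold never turns fail into pass
    expect_false(!g$pass && snr_gate(noise, threshold = 10)$pass)
  }
})

test_that("robust Gaussian centre fitting is exact, robust and equivariant", {
  u <- seq(0, 12, length.out = 60L)
  fit <- fit_center(gauss_profile(u))
  expect_true(fit$converged)
  expect_equal(fit$center, 5.3, tolerance = 1e-6)
  expect_equal(fit$sigma, 1.2, tolerance = 1e-4)
  # single 10x outlier: robust fit stays within 0.1 px, and beats the
  # unweighted fit
  z <- gauss_profile(u)$intensities
  z[20L] <- z[20L] * 10
  rob <- fit_center(intensity_profile(u, z))
  expect_lt(abs(rob$center - 5.3), 0.1)
  plain <- stats::nls(z ~ a + b * exp(-(u - mu)^2 / (2 * s^2)),
                      start = list(a = 10, b = 100, mu = 5.3, s = 1.2))
  expect_gt(abs(coef(plain)[["mu"]] - 5.3), abs(rob$center - 5.3))
  # equivariance: shifting the support (same intensities) shifts the centre
  sh <- fit_center(intensity_profile(u + 3.25,
                                     gauss_profile(u)$intensities))
  expect_equal(sh$center - fit$center, 3.25, tolerance = 1e-6)
})

test_that("snr threshold calibration reports a finite threshold and sweep", {
  cal <- calibrate_snr_threshold(noise_sd = c(2, 8, 24), n_rep = 10L,
                                 seed = 5L)
  expect_true(is.finite(cal$threshold))
  expect_equal(nrow(cal$sweep), 3L)
  # fit error grows with noise
  expect_lt(cal$sweep$median_abs_error[1L], cal$sweep$median_abs_error[3L])
})
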