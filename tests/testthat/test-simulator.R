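test_that("simulation runs are bit-reproducible and respect temperature", {
  cfg <- filament_sim_config(n_beads = 12L, L = 11, Lp = 1, kT = 0.5,
                             dt = 0.02, substeps = 5L, n_frames = 30L,
                             seed = 5L)
  a <- simulate_filament_dynamics(cfg)
  b <- simulate_filament_dynamics(cfg)
  expect_identical(
    lapply(a$contours, `[[`, "points"),
    lapply(b$contours, `[[`, "points"))
  # zero temperature, no forcing: static
  cfg0 <- filament_sim_config(n_beads = 12L, L = 11, Lp = 1, kT = 0,
                              dt = 0.02, substeps = 5L, n_frames = 10L)
  s0 <- simulate_filament_dynamics(cfg0)
  expect_equal(s0$contours[[10L]]$points, s0$contours[[1L]]$points,
               tolerance = 1e-15)
})

test_that("unstable time steps are rejected with advice", {
  expect_error(
    simulate_filament_dynamics(
      filament_sim_config(n_beads = 12L, L = 11, Lp = 100, dt = 0.5,
                          substeps = 1L, n_frames = 5L)),
    "dt")
})

test_that("pinned thermal modes satisfy equipartition", {
  # pinned filament, tension only: sine modes with <b_q^2> = 2 kT L /
  # (T q^2 pi^2); sampled every ~2.5 relaxation times of mode 1
  kT <- 0.25; Ten <- 3; L <- 15
  cfg <- filament_sim_config(n_beads = 16L, L = L, Lp = 1e-4, tension = Ten,
                             kT = kT, dt = 0.05, substeps = 400L,
                             n_frames = 400L, ends = "pinned", seed = 30L)
  ser <- simulate_filament_dynamics(cfg)
  Y <- t(vapply(ser$contours, function(ct) ct$points[, 2L], numeric(16L)))
  x <- ser$contours[[1L]]$points[, 1L]
  ds <- diff(x)[1L]
  for (q in 1:2) {
    bq <- (2 / L) * Y %*% (sin(q * pi * x / L) * ds)
    expect_equal(mean(bq^2), 2 * kT * L / (Ten * q^2 * pi^2),
                 tolerance = 0.2)
  }
})

test_that("the renderer draws a Gaussian cross-section at the line", {
  truth <- contour_series(list(straight_contour(c(4, 20.3), c(44, 20.3),
                                                n = 20L)))
  rc <- render_config(image_size = c(48L, 48L), psf_sigma = 1.5,
                      peak = 100, background = 10, noise = "none")
  img <- render_video(truth, rc)$video[, , 1L]
  # column cut away from the ends
  cut <- img[, 25L] - 10
  ys <- 0:47
  fit <- stats::nls(cut ~ b * exp(-(ys - mu)^2 / (2 * s^2)),
                    start = list(b = 90, mu = 20, s = 1.5))
  expect_lt(abs(coef(fit)[["mu"]] - 20.3), 0.05)
  expect_equal(coef(fit)[["s"]], 1.5, tolerance = 0.02)
  expect_equal(coef(fit)[["b"]], 100, tolerance = 0.03)
  # filament leaving the frame is an error
  out <- contour_series(list(straight_contour(c(-2, 20), c(44, 20))))
  expect_error(render_video(out, rc), "exits")
})

test_that("measured SNR rises monotonically as rendering noise falls", {
  truth <- contour_series(list(straight_contour(c(4, 16), c(28, 16),
                                                n = 20L)))
  snrs <- vapply(c(16, 8, 4, 2), function(ns) {
    vid <- render_video(truth, render_config(image_size = c(32L, 32L),
                                             peak = 120, gaussian_sd = ns,
                                             seed = 7L))$video
    prof <- krig_upsample(extract_profile(vid[, , 1L],
                                          rbind(c(16, 8), c(16, 24)),
                                          n_samples = 17L))
    snr_gate(prof, threshold = 0)$snr
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("rendering, tracking and decomposing preserves mode statistics", {
  cfg <- filament_sim_config(n_beads = 40L, L = 39, Lp = 5, tension = 90,
                             kT = 6, dt = 0.001, substeps = 100L,
                             n_frames = 25L, burn_in = 60L,
                             ends = "pinned", seed = 14L)
  ser <- simulate_filament_dynamics(cfg)
  shifted <- contour_series(lapply(ser$contours, function(ct)
    filament_contour(cbind(ct$points[, 1L] + 12, ct$points[, 2L] + 28))),
    times = ser$times)
  vid <- render_video(shifted, render_config(image_size = c(56L, 64L),
                                             peak = 200, gaussian_sd = 1,
                                             seed = 2L))$video
  tracked <- track_contour_video(vid, rbind(c(12, 28), c(51, 28)),
                                 pixel_size = 1, n_points = 40L)
  ms_truth <- decompose_series(shifted, n_max = 4L)
  ms_track <- decompose_series(tracked, n_max = 4L)
  # total curvature-mode energy (modes >= 1) within 25% of ground truth
  v_truth <- apply(ms_truth$amplitudes[, -1L], 2L, var)
  v_track <- apply(ms_track$amplitudes[, -1L], 2L, var)
  expect_lt(abs(sum(v_track) - sum(v_truth)) / sum(v_truth), 0.25)
  # and the per-mode amplitude time series track the truth
  ac <- vapply(seq_len(4L), function(j)
    cor(ms_truth$amplitudes[, j + 1L], ms_track$amplitudes[, j + 1L]),
    numeric(1))
  expect_gt(min(ac), 0.9)
})

test_that("video TIFF round trip preserves intensities", {
  set.seed(3)
  vid <- array(runif(16 * 16 * 4, 0, 200), c(16L, 16L, 4L))
  f <- tempfile(fileext = ".tif")
  sc <- write_video_tiff(vid, f)
  back <- read_video_tiff(f, scale = sc)
  expect_equal(back, vid, tolerance = 1e-6)
})
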