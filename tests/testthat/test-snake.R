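rms_to_curve <- function(points, curve) {
  sqrt(mean(apply(points, 1L, function(p)
    min((p[1L] - curve[, 1L])^2 + (p[2L] - curve[, 2L])^2))))
}

test_that("the snake settles onto a rendered straight ridge", {
  truth <- contour_series(list(straight_contour(c(6, 24), c(42, 24),
                                                n = 30L)))
  img <- render_video(truth, render_config(image_size = c(48L, 48L),
                                           noise = "none"))$video[, , 1L]
  dense <- cbind(seq(6, 42, length.out = 400L), 24)
  # initialised exactly on the ridge: stays there
  on_ridge <- evolve_open_contour(img, straight_contour(c(6, 24), c(42, 24),
                                                        n = 37L))
  expect_lt(rms_to_curve(on_ridge$points, dense), 0.3)
  # initialised 2 px off laterally: converges onto the ridge
  off <- evolve_open_contour(img, straight_contour(c(6, 26), c(42, 26),
                                                   n = 37L))
  expect_lt(rms_to_curve(off$points, dense), 0.5)
})

test_that("with no image features the contour straightens toward its chord", {
  img <- matrix(5, 48L, 48L)
  t <- seq(0, 1, length.out = 31L)
  bent <- filament_contour(cbind(8 + 32 * t, 24 + 5 * sin(pi * t)))
  out <- evolve_open_contour(img, bent,
                             snake_params(max_iter = 1000L, kappa = 0,
                                          gamma = 0.05, tol = 1e-4))
  chord_dev <- function(p) {
    a <- p[1L, ]; b <- p[nrow(p), ]
    d <- b - a; d <- d / sqrt(sum(d^2))
    mean(abs((p[, 1L] - a[1L]) * d[2L] - (p[, 2L] - a[2L]) * d[1L]))
  }
  expect_lt(chord_dev(out$points), chord_dev(bent$points) / 2)
})

test_that("a statically curved tubule is tracked through a noisy video", {
  t <- seq(0, 1, length.out = 40L)
  pts <- cbind(8 + 32 * t, 24 + 4 * sin(pi * t))
  truth <- contour_series(rep(list(filament_contour(pts)), 25L))
  vid <- render_video(truth, render_config(image_size = c(48L, 48L),
                                           peak = 150, gaussian_sd = 2,
                                           seed = 3L))$video
  series <- track_contour_video(vid, rbind(pts[1L, ], pts[40L, ]),
                                pixel_size = 1)
  dense <- cbind(8 + 32 * seq(0, 1, length.out = 500L),
                 24 + 4 * sin(pi * seq(0, 1, length.out = 500L)))
  errs <- vapply(series$contours, function(ct)
    rms_to_curve(ct$points, dense), numeric(1))
  expect_gt(mean(errs < 0.5), 0.95)
})

test_that("a single-frame video reduces to one contour evolution", {
  truth <- contour_series(list(straight_contour(c(6, 20), c(40, 20),
                                                n = 20L)))
  vid <- render_video(truth, render_config(image_size = c(48L, 48L),
                                           noise = "none"))$video
  series <- track_contour_video(vid, rbind(c(6, 20), c(40, 20)),
                                pixel_size = 1)
  expect_equal(length(series), 1L)
  dense <- cbind(seq(6, 40, length.out = 300L), 20)
  expect_lt(rms_to_curve(series$contours[[1L]]$points, dense), 0.3)
})

test_that("tracked fluctuations follow the rendered ground truth", {
  # equilibrated tension-held filament, rendered and re-tracked; the
  # fluctuation spectrum is dominated by wavelengths the imaging resolves
  cfg <- filament_sim_config(n_beads = 40L, L = 39, Lp = 5, tension = 90,
                             kT = 6, dt = 0.001, substeps = 100L,
                             n_frames = 25L, burn_in = 60L,
                             ends = "pinned", seed = 8L)
  ser <- simulate_filament_dynamics(cfg)
  # place into a 56x64 image frame
  shifted <- lapply(ser$contours, function(ct)
    filament_contour(cbind(ct$points[, 1L] + 12, ct$points[, 2L] + 28)))
  truth <- contour_series(shifted, times = ser$times)
  vid <- render_video(truth, render_config(image_size = c(56L, 64L),
                                           peak = 200, gaussian_sd = 1,
                                           seed = 4L))$video
  tracked <- track_contour_video(vid, rbind(c(12, 28), c(51, 28)),
                                 pixel_size = 1, n_points = 40L)
  # per-point transverse displacement correlates with truth (tracked y
  # interpolated at the truth bead positions)
  Yt <- t(vapply(truth$contours, function(ct) ct$points[, 2L],
                 numeric(40L)))
  Xt <- truth$contours[[1L]]$points[, 1L]
  Yk <- t(vapply(tracked$contours, function(ct)
    stats::approx(ct$points[, 1L], ct$points[, 2L], xout = Xt,
                  rule = 2L)$y, numeric(40L)))
  cors <- vapply(4:37, function(k) cor(Yt[, k], Yk[, k]), numeric(1))
  expect_gt(median(cors), 0.95)
})
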