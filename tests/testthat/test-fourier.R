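uniform_contour_from_theta <- function(theta, ds = 1) {
  x <- c(0, cumsum(ds * cos(theta)))
  y <- c(0, cumsum(ds * sin(theta)))
  filament_contour(cbind(x, y))
}

test_that("tangent geometry follows the segment definitions", {
  horiz <- straight_contour(c(0, 0), c(10, 0), n = 11L)
  g <- tangent_geometry(horiz)
  expect_true(all(g$theta == 0))
  diag45 <- straight_contour(c(0, 0), c(5, 5), n = 6L)
  expect_equal(tangent_geometry(diag45)$theta, rep(pi / 4, 5L),
               tolerance = 1e-12)
  # 3 collinear unit-spaced points: ds = {1,1}, s = {0.5, 1.5}
  g3 <- tangent_geometry(filament_contour(rbind(c(0, 0), c(1, 0), c(2, 0))))
  expect_equal(g3$ds, c(1, 1))
  expect_equal(g3$s, c(0.5, 1.5))
  expect_equal(g3$L, 2)
})

test_that("mode amplitudes match analytic profiles", {
  # constant tangent angle 0.2 over L = 2: a0 = 0.4, higher modes ~ 0
  g <- list(theta = rep(0.2, 50L), ds = rep(2 / 50, 50L),
            s = (1:50 - 0.5) * 2 / 50, L = 2, N = 50L)
  a <- decompose_modes(g, n_max = 6L)
  expect_equal(unname(a["a0"]), 0.4, tolerance = 1e-12)
  expect_true(all(abs(a[-1L]) < 1e-3))
  # single first mode: theta(s) = sqrt(2/L) 0.3 cos(pi s / L)
  L <- 2; n <- 50L
  s <- (1:n - 0.5) * L / n
  g1 <- list(theta = sqrt(2 / L) * 0.3 * cos(pi * s / L),
             ds = rep(L / n, n), s = s, L = L, N = n)
  a1 <- decompose_modes(g1, n_max = 6L)
  expect_equal(unname(a1["a1"]), 0.3, tolerance = 1e-3)
  expect_true(all(abs(a1[-2L]) < 1e-3))
  # constant curvature arc theta(s) = c s: odd modes -2 sqrt(2) c
  # L^(3/2) / (n pi)^2, even modes 0
  cc <- 0.15; L <- 4; n <- 200L
  s <- (1:n - 0.5) * L / n
  ga <- list(theta = cc * s, ds = rep(L / n, n), s = s, L = L, N = n)
  aa <- decompose_modes(ga, n_max = 5L)
  for (k in c(1L, 3L, 5L))
    expect_equal(unname(aa[paste0("a", k)]),
                 -2 * sqrt(2) * cc * L^1.5 / (k^2 * pi^2),
                 tolerance = abs(2 * sqrt(2) * cc * L^1.5 / pi^2) * 0.01)
  expect_lt(max(abs(aa[c("a2", "a4")])), 1e-3)
})

test_that("mode counts respect the sampling caps", {
  g <- tangent_geometry(straight_contour(c(0, 0), c(8, 0), n = 9L))
  # N = 8 segments, max ds = 1, L = 8: caps are L/ds = 8 and N - 2 = 6
  expect_equal(max_modes(g, requested = 10L), 6L)
  expect_warning(a <- decompose_modes(g, n_max = 10L), "caps")
  expect_length(a, 7L)  # a0..a6
})

test_that("reconstruction inverts decomposition on retained modes", {
  # a0-only reconstruction is the constant profile
  th <- reconstruct_tangent(c(a0 = 0.4), s = c(0.5, 1.5), L = 2)
  expect_equal(th, rep(0.2, 2L), tolerance = 1e-12)
  # smooth contour round trip: RMS tangent error < 0.05 rad at 10 modes
  n <- 40L; L <- n
  s <- (1:n - 0.5)
  theta <- 0.4 * cos(pi * s / L) - 0.2 * cos(3 * pi * s / L) +
    0.1 * sin(s / 6)
  fc <- uniform_contour_from_theta(theta)
  g <- tangent_geometry(fc)
  a <- decompose_modes(g, n_max = 10L)
  th_rec <- reconstruct_tangent(a, g$s, g$L)
  expect_lt(sqrt(mean((th_rec - g$theta)^2)), 0.05)
  # projection: decompose(reconstruct(.)) equals the first pass
  fc2 <- uniform_contour_from_theta(th_rec)
  g2 <- tangent_geometry(fc2)
  a2 <- decompose_modes(g2, n_max = 10L)
  expect_equal(a2, a, tolerance = 1e-10)
  # truncation only removes energy (Parseval-style)
  energy <- function(th, ds) sum(th^2 * ds)
  expect_lte(energy(th_rec, g$ds), energy(g$theta, g$ds) + 1e-12)
})

test_that("amplitudes transform correctly under rigid motions", {
  theta <- 0.3 * cos(pi * ((1:40) - 0.5) / 40) + 0.05 * sin((1:40) / 5)
  fc <- uniform_contour_from_theta(theta)
  a <- decompose_modes(tangent_geometry(fc), n_max = 8L)
  # translation: no change at all
  sh <- transform_contour(fc, angle = 0, shift = c(12, -3))
  expect_equal(decompose_modes(tangent_geometry(sh), n_max = 8L), a,
               tolerance = 1e-9)
  # rotation by phi: only a0 changes, by phi * sqrt(2 L)
  phi <- 0.4
  rot <- transform_contour(fc, angle = phi)
  a_rot <- decompose_modes(tangent_geometry(rot), n_max = 8L)
  g <- tangent_geometry(fc)
  expect_equal(unname(a_rot["a0"] - a["a0"]), phi * sqrt(2 * g$L),
               tolerance = 1e-9)
  expect_equal(a_rot[-1L], a[-1L], tolerance = 1e-9)
})

test_that("sustained curvature flags follow the mean-vs-spread rule", {
  nf <- 60L
  # constant non-zero first mode: sustained (zero variance)
  amps <- cbind(a0 = rnorm(nf, 0, 0.1), a1 = rep(0.3, nf),
                a2 = rnorm(nf, 0, 0.05))
  sc <- sustained_curvature(amps)
  expect_true(sc$sustained)
  expect_true(sc$per_mode$sustained[sc$per_mode$mode == 1L])
  # mean = 2 sd: sustained by arithmetic (2 sd - 1.5 sd > 0)
  set.seed(5)
  a1 <- rnorm(5000L)
  a1 <- (a1 - mean(a1)) / sd(a1)        # exact moments
  amps2 <- cbind(a0 = 0, a1 = 0.2 * a1 + 0.4)  # sd 0.2, mean 0.4
  expect_true(sustained_curvature(amps2)$sustained)
  # mode 0 alone never triggers the flag
  amps3 <- cbind(a0 = rep(5, nf), a1 = rnorm(nf))
  set.seed(6)
  expect_false(sustained_curvature(amps3)$sustained)
})

test_that("zero-mean amplitude noise is almost never called sustained", {
  set.seed(99)
  hits <- replicate(1000L, {
    a1 <- rnorm(500L)
    abs(mean(a1)) - 1.5 * sd(a1) > 0
  })
  expect_lt(mean(hits), 0.01)
})

test_that("mode series decomposition covers whole tracked series", {
  Y <- 0.5 * outer(sin(seq(0, pi, length.out = 25L)),
                   sin(seq_len(14L) * pi / 15))
  ser <- contour_series(lapply(1:25, function(f)
    filament_contour(cbind(0:13, Y[f, ]))))
  ms <- decompose_series(ser, n_max = 10L)
  expect_s3_class(ms, "mode_series")
  expect_equal(nrow(ms$amplitudes), 25L)
  expect_equal(ms$n_max, min(10L, 13L - 2L))
  sc <- sustained_curvature(ms)
  expect_true(is.logical(sc$sustained))
})
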