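#' Sample a static worm-like chain
#'
#' Tangent-angle random walk in the plane with step variance set by the
#' persistence length.  Two conventions are supported: `"2D"` gives the
#' planar worm-like chain whose tangent correlation decays as
#' exp(-s / (2 Lp)) (angular step variance ds / Lp), and `"eq1"` scales the
#' step variance to 2 ds / Lp so that the tangent correlation decays as
#' exp(-s / Lp) and the ensemble mean square end-to-end distance follows
#' the Kratky-Porod relation [wlc_r2()] exactly.
#'
#' @param Lp persistence length (same length unit as `L`).
#' @param L contour length.
#' @param n_points number of contour points (>= 3).
#' @param convention `"eq1"` (default) or `"2D"`.
#' @param seed optional RNG seed for a reproducible chain.
#' @param pixel_size stored pixel size (default 1: coordinates are in the
#'   physical length unit).
#' @return A [filament_contour()] starting at the origin with initial
#'   tangent along +x.
#' @export
sample_wlc <- function(Lp, L, n_points = 50L, convention = c("eq1", "2D"),
                       seed = NULL, pixel_size = 1) {
  convention <- match.arg(convention)
  stopifnot(Lp > 0, L > 0)
  if (n_points < 3L) stop("n_points must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  n_seg <- n_points - 1L
  ds <- L / n_seg
  sdev <- sqrt(if (convention == "eq1") 2 * ds / Lp else ds / Lp)
  theta <- cumsum(c(0, rnorm(n_seg - 1L, 0, sdev)))
  x <- c(0, cumsum(ds * cos(theta)))
  y <- c(0, cumsum(ds * sin(theta)))
  filament_contour(cbind(x, y), pixel_size = pixel_size)
}

#' Ensemble of worm-like chain (L, R) pairs
#'
#' Samples many chains per contour length and returns their contour length
#' and end-to-end distance, the input to [fit_persistence_length()].
#'
#' @param Lp persistence length.
#' @param Ls vector of contour lengths.
#' @param n_rep chains per contour length.
#' @param n_points points per chain.
#' @param convention see [sample_wlc()].
#' @param seed RNG seed.
#' @return Data frame with columns `L_um`, `R_um`.
#' @export
wlc_ensemble <- function(Lp, Ls, n_rep = 100L, n_points = 50L,
                         convention = c("eq1", "2D"), seed = NULL) {
  convention <- match.arg(convention)
  if (!is.null(seed)) set.seed(seed)
  n_seg <- n_points - 1L
  out <- lapply(Ls, function(L) {
    ds <- L / n_seg
    sdev <- sqrt(if (convention == "eq1") 2 * ds / Lp else ds / Lp)
    dth <- matrix(rnorm(n_rep * (n_seg - 1L), 0, sdev), nrow = n_seg - 1L)
    theta <- rbind(0, apply(dth, 2L, cumsum))      # n_seg x n_rep
    Rx <- ds * colSums(cos(theta))
    Ry <- ds * colSums(sin(theta))
    data.frame(L_um = L, R_um = sqrt(Rx^2 + Ry^2))
  })
  do.call(rbind, out)
}

#' Configuration for the dynamic filament simulator
#'
#' The simulator integrates the overdamped transverse dynamics of a
#' semiflexible filament held along the x-axis (weakly-bending
#' representation): per bead,
#' \deqn{\gamma_b \, dy = (F_{bend} + F_{tension} + F_{active}) dt +
#'   \sqrt{2 k_B T \gamma_b \, dt}\; \eta}
#' with bending force from the discrete squared-curvature energy (rigidity
#' kappa = Lp * kT) and tension force from the discrete stretching energy.
#' Active forcing is an on/off telegraph process at chosen beads: bursts
#' with mean duration `tau_on` separated by quiet intervals with mean
#' duration `tau_off`, pushing with constant amplitude in the `bias`
#' direction.  Bursty one-sided forcing produces the skewed transverse
#' displacements characteristic of motor or contact-site driven tubules,
#' while thermal noise alone gives symmetric displacements.
#'
#' @param n_beads number of beads.
#' @param L filament length, micrometres.
#' @param Lp persistence length, micrometres (sets kappa = Lp * kT).
#' @param tension uniform tension, kT per micrometre (>= 0).
#' @param kT thermal energy scale (default 1).
#' @param drag drag coefficient per unit length, kT s / um^2.
#' @param dt integration time step, seconds.
#' @param substeps integration steps per stored frame.
#' @param n_frames number of stored frames.
#' @param burn_in frames integrated and discarded before recording starts
#'   (equilibration; default 0, the filament starts straight).
#' @param ends `"free"` or `"pinned"` (both endpoint beads held at y = 0).
#' @param active `NULL`, or a list with `sites` (bead indices),
#'   `amplitude` (force, kT/um), `tau_on`, `tau_off` (seconds), and `bias`
#'   (+1 or -1, the forcing direction in y).
#' @param pixel_size micrometres per pixel used when exporting contours.
#' @param seed RNG seed.
#' @return Named list of class `filament_sim_config`.
#' @export
filament_sim_config <- function(n_beads = 64L, L = 63, Lp = 10,
                                tension = 0, kT = 1, drag = 1,
                                dt = 0.0025, substeps = 20L,
                                n_frames = 30000L, burn_in = 0L,
                                ends = c("free", "pinned"), active = NULL,
                                pixel_size = 0.104, seed = 1L) {
  ends <- match.arg(ends)
  stopifnot(n_beads >= 4L, L > 0, Lp > 0, tension >= 0, kT >= 0,
            drag > 0, dt > 0, substeps >= 1L, n_frames >= 1L,
            burn_in >= 0L)
  if (!is.null(active)) {
    need <- c("sites", "amplitude", "tau_on", "tau_off", "bias")
    miss <- setdiff(need, names(active))
    if (length(miss))
      stop("active forcing spec missing: ", paste(miss, collapse = ", "))
  }
  structure(list(n_beads = as.integer(n_beads), L = L, Lp = Lp,
                 tension = tension, kT = kT, drag = drag, dt = dt,
                 substeps = as.integer(substeps),
                 n_frames = as.integer(n_frames),
                 burn_in = as.integer(burn_in), ends = ends,
                 active = active, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "filament_sim_config")
}

# transpose-difference helpers: t(D2) %*% v and t(D1) %*% v for length-N output
crossprod_d2 <- function(v, N) {
  f <- numeric(N)
  n <- length(v)
  f[seq_len(n)] <- f[seq_len(n)] + v
  f[seq_len(n) + 1L] <- f[seq_len(n) + 1L] - 2 * v
  f[seq_len(n) + 2L] <- f[seq_len(n) + 2L] + v
  f
}
crossprod_d1 <- function(v, N) {
  f <- numeric(N)
  n <- length(v)
  f[seq_len(n)] <- f[seq_len(n)] - v
  f[seq_len(n) + 1L] <- f[seq_len(n) + 1L] + v
  f
}

#' Simulate transverse dynamics of a semiflexible filament
#'
#' Overdamped Langevin integration of the bead chain described in
#' [filament_sim_config()].  The output is a ground-truth
#' [contour_series()]: beads sit at fixed x positions along the filament
#' axis and fluctuate in y.  Runs are bit-reproducible for a given
#' configuration (the seed is part of the configuration).
#'
#' In the untensioned thermal regime the transverse mean squared
#' displacement of an interior point grows as tau^(3/4) at lags between
#' the shortest and longest bending relaxation times; in the
#' tension-dominated regime it grows as tau^(1/2).
#'
#' @param config a [filament_sim_config()].
#' @param coordinates `"um"` (default) or `"px"` (divide by `pixel_size`,
#'   for rendering).
#' @return A [contour_series()] with `config` attached as attribute
#'   `sim_config`.
#' @export
simulate_filament_dynamics <- function(config, coordinates = c("um", "px")) {
  stopifnot(inherits(config, "filament_sim_config"))
  coordinates <- match.arg(coordinates)
  set.seed(config$seed)
  N <- config$n_beads
  ds <- config$L / (N - 1L)
  kappa <- config$Lp * max(config$kT, .Machine$double.eps)
  gamma_b <- config$drag * ds
  # explicit-Euler stability: dt * lambda_max / gamma_b < 2
  lambda_max <- 16 * kappa / ds^3 + 4 * config$tension / ds
  if (config$dt * lambda_max / gamma_b >= 2)
    stop(sprintf(
      "unstable time step: reduce dt below %.3g s for these parameters",
      2 * gamma_b / lambda_max))
  pinned <- config$ends == "pinned"
  y <- numeric(N)
  noise_sd <- sqrt(2 * config$kT * config$dt / gamma_b)
  act <- config$active
  act_on <- FALSE
  frames <- vector("list", config$n_frames)
  x <- (seq_len(N) - 1L) * ds
  cb <- kappa / ds^3
  ct <- config$tension / ds
  max_step <- 0
  burn <- if (is.null(config$burn_in)) 0L else config$burn_in
  for (fr in seq_len(burn + config$n_frames)) {
    for (ss in seq_len(config$substeps)) {
      F <- -cb * crossprod_d2(diff(y, differences = 2L), N)
      if (ct > 0) F <- F - ct * crossprod_d1(diff(y), N)
      if (!is.null(act)) {
        # telegraph switching (exponential dwell times via per-step rates)
        p_switch <- config$dt / (if (act_on) act$tau_on else act$tau_off)
        if (runif(1) < p_switch) act_on <- !act_on
        if (act_on)
          F[act$sites] <- F[act$sites] + act$amplitude * act$bias
      }
      dy_det <- F / gamma_b * config$dt
      step <- abs(dy_det)
      if (max(step) > ds)
        stop(sprintf(
          "integration diverging (bead moved %.2g um > ds = %.2g um); reduce dt",
          max(step), ds))
      max_step <- max(max_step, max(step))
      y <- y + dy_det + noise_sd * rnorm(N)
      if (pinned) { y[1L] <- 0; y[N] <- 0 }
    }
    if (fr > burn) frames[[fr - burn]] <- y
  }
  scale <- if (coordinates == "px") 1 / config$pixel_size else 1
  px_size <- if (coordinates == "px") config$pixel_size else 1
  contours <- lapply(seq_along(frames), function(i)
    filament_contour(cbind(x, frames[[i]]) * scale, pixel_size = px_size,
                     frame_index = i))
  out <- contour_series(
    contours,
    times = (seq_len(config$n_frames) - 1L) * config$dt * config$substeps,
    params = list(simulator = unclass(config)))
  attr(out, "sim_config") <- config
  out
}

#' Reference simulation conditions for the dynamic regimes
#'
#' Frozen configurations (in reduced units: bead spacing 1, kT 1, drag 1
#' per unit length) used to validate the MSD pipeline against theory:
#'
#' * `thermal_filament_config()`: untensioned semiflexible filament with
#'   free ends; the midpoint transverse MSD grows as tau^(3/4) at
#'   intermediate lags.
#' * `tensioned_filament_config()`: tension-dominated filament (bending
#'   negligible at all resolved wavelengths); exponent 1/2.
#' * `thermal_control_config()`: short pinned tensioned filament sampled at
#'   intervals long compared to its slowest relaxation time, the null
#'   (symmetric-fluctuation) control for the skewness test.
#' * `kicked_filament_config()`: the same filament with bursty one-sided
#'   active forcing at its middle bead, which produces significantly
#'   skewed transverse displacements at the forced site.
#'
#' @param seed RNG seed.
#' @return A [filament_sim_config()].
#' @name sim_conditions
NULL

#' @rdname sim_conditions
#' @export
thermal_filament_config <- function(seed = 1L) {
  filament_sim_config(n_beads = 64L, L = 63, Lp = 10, tension = 0,
                      kT = 1, drag = 1, dt = 0.0025, substeps = 20L,
                      n_frames = 30000L, ends = "free", seed = seed)
}

#' @rdname sim_conditions
#' @export
tensioned_filament_config <- function(seed = 1L) {
  filament_sim_config(n_beads = 64L, L = 63, Lp = 0.01, tension = 4,
                      kT = 1, drag = 1, dt = 0.01, substeps = 5L,
                      n_frames = 10000L, ends = "free", seed = seed)
}

#' @rdname sim_conditions
#' @export
thermal_control_config <- function(seed = 1L) {
  filament_sim_config(n_beads = 16L, L = 15, Lp = 0.1, tension = 3,
                      kT = 0.1, drag = 1, dt = 0.1, substeps = 200L,
                      n_frames = 150L, ends = "pinned", seed = seed)
}

#' @rdname sim_conditions
#' @export
kicked_filament_config <- function(seed = 1L, site = 8L, amplitude = 3,
                                   tau_on = 6, tau_off = 34, bias = 1) {
  filament_sim_config(n_beads = 16L, L = 15, Lp = 0.1, tension = 3,
                      kT = 0.1, drag = 1, dt = 0.1, substeps = 200L,
                      n_frames = 150L, ends = "pinned",
                      active = list(sites = site, amplitude = amplitude,
                                    tau_on = tau_on, tau_off = tau_off,
                                    bias = bias),
                      seed = seed)
}

#' Slowest relaxation time of a simulated filament
#'
#' Estimated from the lowest non-trivial mode of the configured restoring
#' forces: wavenumber k1 = 4.73/L for free ends (free-free flexural mode)
#' or pi/L for pinned ends, with rate (kappa k1^4 + tension k1^2) / drag.
#'
#' @param config a [filament_sim_config()].
#' @return Relaxation time in seconds.
#' @export
filament_relaxation_time <- function(config) {
  stopifnot(inherits(config, "filament_sim_config"))
  k1 <- (if (config$ends == "free") 4.73 else pi) / config$L
  kappa <- config$Lp * config$kT
  rate <- (kappa * k1^4 + config$tension * k1^2) / config$drag
  1 / rate
}

#' Intermediate-lag fit window for filament MSD exponents
#'
#' The power-law regimes hold between the shortest and longest relaxation
#' times of the filament, and a time-averaged MSD is only reliable at lags
#' well below the track duration.  The window runs from 10 frame intervals
#' up to the smaller of a quarter of the slowest relaxation time and 1% of
#' the track duration.
#'
#' @param config a [filament_sim_config()].
#' @return Length-2 numeric lag-time window in seconds.
#' @export
intermediate_lag_window <- function(config) {
  dtf <- config$dt * config$substeps
  duration <- config$n_frames * dtf
  c(10 * dtf, min(filament_relaxation_time(config) / 4, duration / 100))
}

#' Extract the trajectory of one backbone point as a tracked series
#'
#' Convenience bridge from a simulated (or tracked) [contour_series()] to
#' the [tracked_points()] format consumed by [compute_msd()].
#'
#' @param series a [contour_series()].
#' @param point bead/point index; default the midpoint.
#' @return A [tracked_points()] series (all frames valid).
#' @export
point_track_from_series <- function(series, point = NULL) {
  stopifnot(inherits(series, "contour_series"))
  K <- nrow(series$contours[[1L]]$points)
  if (is.null(point)) point <- (K + 1L) %/% 2L
  xs <- vapply(series$contours, function(ct) ct$points[point, 1L],
               numeric(1))
  ys <- vapply(series$contours, function(ct) ct$points[point, 2L],
               numeric(1))
  dt <- if (length(series$times) > 1L) diff(series$times)[1L] else 1
  tracked_points(
    data.frame(frame = seq_along(xs), t = series$times,
               position_px = ys, x = xs, y = ys, valid = TRUE, snr = Inf),
    pixel_size = series$pixel_size, frame_interval = dt)
}

#' Simulate a two-dimensional Brownian point track
#'
#' Gaussian displacement increments with variance 2 D dt per axis; the MSD
#' slope is 4 D and the anomalous exponent is 1.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param dt frame interval, seconds.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A [tracked_points()] series with coordinates in micrometres
#'   (`pixel_size = 1`).
#' @export
simulate_brownian_track <- function(D, dt, n_frames, seed = 1L) {
  stopifnot(D >= 0, dt > 0, n_frames >= 2L)
  set.seed(seed)
  sdev <- sqrt(2 * D * dt)
  x <- cumsum(c(0, rnorm(n_frames - 1L, 0, sdev)))
  y <- cumsum(c(0, rnorm(n_frames - 1L, 0, sdev)))
  tracked_points(
    data.frame(frame = seq_len(n_frames), t = (seq_len(n_frames) - 1L) * dt,
               position_px = y, x = x, y = y, valid = TRUE, snr = Inf),
    pixel_size = 1, frame_interval = dt)
}
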