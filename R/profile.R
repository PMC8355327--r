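#' Bicubic image interpolation at arbitrary points
#'
#' Catmull-Rom bicubic interpolation (Keys kernel, a = -0.5) of a grayscale
#' image at sub-pixel positions.  Image coordinates place the origin at the
#' centre of the top-left pixel: `x` runs along columns, `y` along rows.
#' Edge pixels are replicated outside the image.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param x,y coordinates of the query points, in pixels.
#' @return Numeric vector of interpolated intensities.
#' @export
bicubic_interp <- function(image, x, y) {
  stopifnot(is.matrix(image), length(x) == length(y))
  nr <- nrow(image); nc <- ncol(image)
  cubic_w <- function(t) {
    at <- abs(t)
    w <- numeric(length(t))
    i1 <- at <= 1
    w[i1] <- 1.5 * at[i1]^3 - 2.5 * at[i1]^2 + 1
    i2 <- at > 1 & at < 2
    w[i2] <- -0.5 * at[i2]^3 + 2.5 * at[i2]^2 - 4 * at[i2] + 2
    w
  }
  ix <- floor(x); iy <- floor(y)
  out <- numeric(length(x))
  for (dy in -1:2) {
    ry <- pmin(pmax(iy + dy, 0), nr - 1)
    wy <- cubic_w(y - (iy + dy))
    acc <- numeric(length(x))
    for (dx in -1:2) {
      rx <- pmin(pmax(ix + dx, 0), nc - 1)
      wx <- cubic_w(x - (ix + dx))
      acc <- acc + wx * image[cbind(ry + 1, rx + 1)]
    }
    out <- out + wy * acc
  }
  out
}

#' Intensity profile along a line
#'
#' @param positions sample positions along the line in pixels, strictly
#'   increasing.
#' @param intensities intensity values, same length.
#' @param endpoints optional 2x2 matrix of the line endpoints (rows = ends,
#'   columns = x, y) for mapping positions back to image coordinates.
#' @param method provenance tag (e.g. "raw", "kriging", "spline").
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, endpoints = NULL,
                              method = "raw") {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) < 4L)
    stop("an intensity profile needs at least 4 samples")
  if (length(positions) != length(intensities))
    stop("positions and intensities differ in length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(!is.finite(intensities)) || any(!is.finite(positions)))
    stop("profile values must be finite")
  structure(list(positions = positions, intensities = intensities,
                 endpoints = endpoints, method = method),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples over [%.2f, %.2f] px (%s)\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$method))
  invisible(x)
}

#' Extract an intensity profile along a line in an image
#'
#' Samples image intensity by bicubic interpolation at `n_samples` evenly
#' spaced positions along the segment between two endpoints, typically drawn
#' perpendicular to a tubule.
#'
#' @param image numeric matrix.
#' @param line_endpoints 2x2 matrix, rows = the two endpoints, columns =
#'   (x, y) in pixels.
#' @param n_samples number of samples (>= 4).
#' @return An [intensity_profile()]; positions are distances along the line
#'   from the first endpoint.
#' @export
extract_profile <- function(image, line_endpoints, n_samples = 25L) {
  line_endpoints <- as.matrix(line_endpoints)
  stopifnot(is.matrix(image), all(dim(line_endpoints) == c(2L, 2L)))
  if (n_samples < 4L) stop("n_samples must be >= 4")
  p0 <- line_endpoints[1L, ]; p1 <- line_endpoints[2L, ]
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length profile line")
  xr <- range(line_endpoints[, 1L]); yr <- range(line_endpoints[, 2L])
  if (xr[1L] < 0 || yr[1L] < 0 ||
      xr[2L] > ncol(image) - 1 || yr[2L] > nrow(image) - 1)
    stop("profile line exits the image bounds")
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1L] + t * (p1[1L] - p0[1L])
  ys <- p0[2L] + t * (p1[2L] - p0[2L])
  intensity_profile(t * len, bicubic_interp(image, xs, ys),
                    endpoints = line_endpoints, method = "raw")
}

#' Upsample an intensity profile by ordinary kriging
#'
#' Exact stochastic-process interpolation of a sparse intensity profile onto
#' `n_out` evenly spaced positions over the same support, using ordinary
#' kriging with a Gaussian covariance model and zero nugget, so the
#' interpolant passes through the raw samples.  When the kriging system is
#' ill-conditioned (condition number above `max_condition`) the function
#' falls back to cubic-spline interpolation and tags the result.
#'
#' @param profile an [intensity_profile()].
#' @param n_out number of output samples (default 100).
#' @param range_factor Gaussian covariance range as a multiple of the mean
#'   sample spacing.
#' @param max_condition condition-number limit for the kriging system.
#' @return An [intensity_profile()] with `n_out` samples; `method` is
#'   "kriging" or "spline" (fallback).
#' @export
krig_upsample <- function(profile, n_out = 100L, range_factor = 2,
                          max_condition = 1e10) {
  stopifnot(inherits(profile, "intensity_profile"))
  u <- profile$positions; z <- profile$intensities
  n <- length(u)
  out_pos <- seq(u[1L], u[n], length.out = n_out)
  rng <- range_factor * mean(diff(u))
  K <- exp(-(outer(u, u, "-") / rng)^2)
  # universal kriging with a linear drift: exact at the samples and exact
  # on constant and linear profiles
  um <- (u - mean(u)) / rng
  A <- rbind(cbind(K, 1, um),
             c(rep(1, n), 0, 0),
             c(um, 0, 0))
  cond <- kappa(A, exact = FALSE)
  if (!is.finite(cond) || cond > max_condition) {
    zi <- spline(u, z, xout = out_pos, method = "fmm")$y
    return(intensity_profile(out_pos, zi, endpoints = profile$endpoints,
                             method = "spline"))
  }
  om <- (out_pos - mean(u)) / rng
  k <- exp(-(outer(u, out_pos, "-") / rng)^2)
  W <- solve(A, rbind(k, 1, om))       # kriging weights + drift multipliers
  zi <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  intensity_profile(out_pos, zi, endpoints = profile$endpoints,
                    method = "kriging")
}

# centred moving-average smoother with edge replication
smooth_profile <- function(z, window = 5L) {
  window <- min(window, length(z))
  if (window %% 2L == 0L) window <- window - 1L
  if (window < 3L) return(z)
  half <- (window - 1L) %/% 2L
  zp <- c(rep(z[1L], half), z, rep(z[length(z)], half))
  as.numeric(stats::filter(zp, rep(1 / window, window), sides = 2L))[
    half + seq_along(z)]
}

#' Signal-to-noise gate for intensity profiles
#'
#' SNR is defined as (peak of the smoothed profile - median of the profile)
#' divided by a robust noise scale, the median absolute deviation (scaled by
#' 1.4826) of the residuals after subtracting the smoothed profile.  A
#' profile passes when its SNR is at least `threshold`.  Zero noise gives
#' SNR = +Inf, which always passes.
#'
#' @param profile an [intensity_profile()].
#' @param threshold minimum acceptable SNR.
#' @param window smoothing window (samples) for the peak estimate; the
#'   default scales with the profile length so that interpolation-scale
#'   wiggles of an upsampled profile count as noise, not signal.
#' @return List with `snr` and logical `pass`.
#' @seealso [calibrate_snr_threshold()] for choosing `threshold`.
#' @export
snr_gate <- function(profile, threshold, window = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  z <- profile$intensities
  if (is.null(window)) window <- max(5L, round(length(z) / 10))
  sm <- smooth_profile(z, window)
  noise <- mad(z - sm)
  if (noise <= 1e-12 * max(1, max(abs(z)))) noise <- 0
  snr <- if (noise == 0) Inf else (max(sm) - median(z)) / noise
  list(snr = snr, pass = snr >= threshold)
}

#' Robust Gaussian-with-offset fit of a tubule intensity profile
#'
#' Fits `a + b * exp(-(u - mu)^2 / (2 sigma^2))` to an intensity profile by
#' iteratively reweighted nonlinear least squares with a Cauchy weight
#' function (tuning constant 2.385), which suppresses the influence of
#' outlying intensity samples.  The tubule position is the fitted centre
#' `mu`.
#'
#' @param profile an [intensity_profile()].
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the centre, pixels.
#' @param cauchy_c Cauchy tuning constant.
#' @return List with `center` (mu, pixels along the line), `stderr`,
#'   `sigma`, `amplitude`, `offset`, `converged`, and `flagged` (TRUE when
#'   the fit is untrustworthy: non-convergence, sigma below 0.5 px, or sigma
#'   wider than the profile span).
#' @export
fit_center <- function(profile, max_iter = 50L, tol = 1e-10,
                       cauchy_c = 2.385) {
  stopifnot(inherits(profile, "intensity_profile"))
  u <- profile$positions; z <- profile$intensities
  span <- diff(range(u))
  start <- list(a = min(z), b = max(z) - min(z),
                mu = u[which.max(smooth_profile(z))],
                sigma = span / 6)
  if (start$b <= 0) start$b <- max(abs(z)) + 1e-6
  w <- rep(1, length(u))
  fit <- NULL; mu_old <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ a + b * exp(-(u - mu)^2 / (2 * sigma^2)),
                        data = data.frame(u = u, z = z),
                        start = start, weights = w,
                        lower = c(-Inf, 0, min(u) - span, 1e-3),
                        upper = c(Inf, Inf, max(u) + span, 10 * span),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) break
    cf <- as.list(coef(fit))
    r <- z - (cf$a + cf$b * exp(-(u - cf$mu)^2 / (2 * cf$sigma^2)))
    s <- mad(r)
    w <- if (s == 0) rep(1, length(u)) else 1 / (1 + (r / (cauchy_c * s))^2)
    if (abs(cf$mu - mu_old) < tol) { converged <- TRUE; break }
    mu_old <- cf$mu
    start <- cf
    if (s == 0) { converged <- TRUE; break }
  }
  if (is.null(fit))
    return(list(center = NA_real_, stderr = NA_real_, sigma = NA_real_,
                amplitude = NA_real_, offset = NA_real_,
                converged = FALSE, flagged = TRUE))
  cf <- as.list(coef(fit))
  se <- tryCatch(sqrt(diag(vcov(fit)))[["mu"]], error = function(e) NA_real_)
  flagged <- !converged || cf$sigma < 0.5 || cf$sigma > span
  list(center = cf$mu, stderr = unname(se), sigma = cf$sigma,
       amplitude = cf$b, offset = cf$a,
       converged = converged, flagged = flagged)
}

#' Calibrate the SNR gate on simulated tubule profiles
#'
#' Sweeps noise levels on synthetic Gaussian tubule cross-sections, measures
#' the SNR reported by [snr_gate()] and the centre-fit error of
#' [fit_center()], and returns the smallest SNR at which the median absolute
#' fit error is at most `target_error_frac` of the tubule width (Gaussian
#' sigma).
#'
#' @param width_px tubule cross-section sigma in pixels.
#' @param amplitude,offset profile peak height above offset, and offset.
#' @param noise_sd numeric vector of Gaussian noise standard deviations to
#'   sweep.
#' @param n_rep profiles per noise level.
#' @param n_raw raw samples per profile before kriging upsampling.
#' @param target_error_frac target median |centre error| as a fraction of
#'   `width_px`.
#' @param seed RNG seed.
#' @return List with `threshold` (calibrated SNR) and `sweep`, a data frame
#'   of per-noise-level median SNR and median absolute fit error.
#' @export
calibrate_snr_threshold <- function(width_px = 2, amplitude = 100,
                                    offset = 10,
                                    noise_sd = c(0.5, 1, 2, 4, 8, 16, 32),
                                    n_rep = 40L, n_raw = 9L,
                                    target_error_frac = 0.01,
                                    seed = 1L) {
  set.seed(seed)
  span <- 8 * width_px
  u <- seq(0, span, length.out = n_raw)
  rows <- lapply(noise_sd, function(ns) {
    snrs <- errs <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      mu <- span / 2 + runif(1, -0.5, 0.5)
      z <- offset + amplitude * exp(-(u - mu)^2 / (2 * width_px^2)) +
        rnorm(n_raw, 0, ns)
      prof <- krig_upsample(intensity_profile(u, z))
      snrs[r] <- snr_gate(prof, threshold = 0)$snr
      ctr <- fit_center(prof)
      errs[r] <- abs(ctr$center - mu)
    }
    data.frame(noise_sd = ns,
               median_snr = median(snrs[is.finite(snrs)]),
               median_abs_error = median(errs, na.rm = TRUE))
  })
  sweep <- do.call(rbind, rows)
  target <- target_error_frac * width_px
  ok <- sweep$median_abs_error <= target
  threshold <- if (any(ok)) min(sweep$median_snr[ok]) else
    max(sweep$median_snr)
  list(threshold = threshold, sweep = sweep)
}
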