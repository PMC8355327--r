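# unwrap radian angles so consecutive values never jump by more than pi
unwrap_angles <- function(theta) {
  d <- diff(theta)
  adj <- cumsum(round(d / (2 * pi))) * 2 * pi
  c(theta[1L], theta[-1L] - adj)
}

#' Tangent-angle geometry of a contour
#'
#' For a contour of n points the k-th of the N = n - 1 segments has tangent
#' angle `theta[k] = atan2(y[k+1] - y[k], x[k+1] - x[k])` (unwrapped to
#' avoid +/- pi jumps), length `ds[k]`, and arclength midpoint
#' `s[k] = sum(ds[1:(k-1)]) + ds[k] / 2`.  Lengths are in pixels.
#'
#' @param contour a [filament_contour()] with at least 3 points.
#' @return List with `theta` (radians), `ds`, `s`, `L` (pixels) and `N`
#'   (number of segments).
#' @export
tangent_geometry <- function(contour) {
  stopifnot(inherits(contour, "filament_contour"))
  p <- contour$points
  if (nrow(p) < 3L) stop("tangent geometry needs at least 3 points")
  d <- diff(p)
  theta <- unwrap_angles(atan2(d[, 2L], d[, 1L]))
  list(theta = theta, ds = contour$ds, s = contour$s,
       L = contour$length_px, N = nrow(p) - 1L)
}

#' Maximum usable Fourier mode number
#'
#' Two sampling rules cap the mode count: at least two segments per mode
#' wavelength (Nyquist), `n <= L / max(ds)` (the largest segment is the
#' conservative choice for non-uniform sampling), and `n <= N - 2` for N
#' segments.  Ten modes are used when both conditions allow it.
#'
#' @param geometry output of [tangent_geometry()].
#' @param requested requested number of modes (default 10).
#' @return Integer mode cap.
#' @export
max_modes <- function(geometry, requested = 10L) {
  as.integer(min(as.integer(requested),
                 floor(geometry$L / max(geometry$ds)),
                 geometry$N - 2L))
}

#' Fourier cosine-mode amplitudes of a tangent-angle profile
#'
#' Discrete approximation of the cosine-mode amplitudes of the tangent
#' angle,
#' \deqn{a_n = \sqrt{2/L} \sum_k \theta_k \, \Delta s_k
#'   \cos(n \pi s_k / L),}
#' for modes n = 0..n_max.  Mode 0 carries the mean orientation of the
#' filament; modes n >= 1 carry its curvature.
#'
#' @param geometry output of [tangent_geometry()], or a
#'   [filament_contour()].
#' @param n_max highest mode; capped (with a warning) at the sampling
#'   limits of [max_modes()].
#' @return Named numeric vector `a0 ... a<n_max>` in radian sqrt(pixels).
#' @export
decompose_modes <- function(geometry, n_max = 10L) {
  if (inherits(geometry, "filament_contour"))
    geometry <- tangent_geometry(geometry)
  cap <- max_modes(geometry, requested = n_max)
  if (cap < 0L) stop("contour too short for any Fourier mode")
  if (n_max > cap) {
    warning(sprintf("n_max = %d exceeds sampling caps; using %d",
                    n_max, cap))
    n_max <- cap
  }
  n <- 0:n_max
  basis <- cos(outer(geometry$s / geometry$L, n * pi))   # k x modes
  amps <- sqrt(2 / geometry$L) *
    drop(crossprod(basis, geometry$theta * geometry$ds))
  names(amps) <- paste0("a", n)
  amps
}

#' Reconstruct a tangent-angle profile from mode amplitudes
#'
#' \deqn{\theta(s_k) = \sqrt{2/L} \left( \tfrac{1}{2} a_0 +
#'   \sum_{n \ge 1} a_n \cos(n \pi s_k / L) \right).}
#' The zeroth (mean orientation) amplitude enters with a factor 1/2, the
#' standard cosine-series convention, which makes
#' decompose -> reconstruct a projection of the tangent profile onto the
#' retained modes.
#'
#' @param amplitudes named vector from [decompose_modes()] (`a0`, `a1`,
#'   ...).
#' @param s arclength midpoints (pixels).
#' @param L contour length (pixels).
#' @return Tangent angles at `s`, radians.
#' @export
reconstruct_tangent <- function(amplitudes, s, L) {
  n <- seq_along(amplitudes) - 1L
  basis <- cos(outer(s / L, n * pi))
  w <- amplitudes
  w[1L] <- w[1L] / 2
  drop(basis %*% w) * sqrt(2 / L)
}

#' Mode amplitude series for a tracked tubule
#'
#' Decomposes every frame of a contour series into Fourier cosine modes.
#' All frames use a common mode cap (the minimum of the per-frame sampling
#' caps and `n_max`).
#'
#' @param series a [contour_series()].
#' @param n_max requested highest mode (default 10).
#' @return Object of class `mode_series`: list with `amplitudes` (frames x
#'   modes matrix, columns `a0`...), `L` (per-frame contour length,
#'   pixels), `times`, `n_max`, `pixel_size`.
#' @export
decompose_series <- function(series, n_max = 10L) {
  stopifnot(inherits(series, "contour_series"))
  geoms <- lapply(series$contours, tangent_geometry)
  cap <- min(vapply(geoms, max_modes, integer(1), requested = n_max))
  if (cap < 1L) stop("series contours too short for curvature modes")
  amps <- t(vapply(geoms, decompose_modes, numeric(cap + 1L),
                   n_max = cap))
  structure(list(amplitudes = amps,
                 L = vapply(geoms, `[[`, numeric(1), "L"),
                 times = series$times, n_max = cap,
                 pixel_size = series$pixel_size),
            class = "mode_series")
}

#' @export
print.mode_series <- function(x, ...) {
  cat(sprintf("<mode_series> %d frames x modes 0..%d\n",
              nrow(x$amplitudes), x$n_max))
  invisible(x)
}

#' Sustained-curvature classification from mode amplitudes
#'
#' A mode shows sustained curvature when the magnitude of its mean
#' amplitude exceeds `multiplier` standard deviations of the amplitude over
#' time: `|mean(a_n)| - multiplier * sd(a_n) > 0`.  Under a Gaussian
#' amplitude distribution this requires the amplitude to fall on one side
#' of zero for roughly 87% of frames or more (at the default multiplier
#' 1.5, interpreted one-sidedly).  Mode 0 (mean orientation) is excluded:
#' any straight but tilted filament has non-zero a_0.  The tubule is
#' classified as having sustained curvature when any mode n >= 1 qualifies.
#'
#' @param series a `mode_series` from [decompose_series()], or a frames x
#'   modes amplitude matrix with columns `a0`, `a1`, ...
#' @param multiplier standard-deviation multiplier (default 1.5).
#' @param min_frames minimum frames required (default 20).
#' @return List with `sustained` (overall flag), `per_mode` data frame
#'   (`mode`, `mean`, `sd`, `margin`, `one_sided_fraction`, `sustained`),
#'   and `n_frames`.
#' @export
sustained_curvature <- function(series, multiplier = 1.5,
                                min_frames = 20L) {
  amps <- if (inherits(series, "mode_series")) series$amplitudes
          else as.matrix(series)
  if (nrow(amps) < min_frames)
    stop("sustained-curvature test needs at least ", min_frames, " frames")
  modes <- colnames(amps)
  if (is.null(modes)) modes <- paste0("a", seq_len(ncol(amps)) - 1L)
  keep <- modes != "a0"
  a <- amps[, keep, drop = FALSE]
  mu <- colMeans(a)
  sdev <- apply(a, 2L, sd)
  margin <- abs(mu) - multiplier * sdev
  # zero-variance series: sustained iff the constant amplitude is non-zero
  sustained <- ifelse(sdev == 0, mu != 0, margin > 0)
  osf <- apply(a, 2L, function(v) max(mean(v > 0), mean(v < 0)))
  per_mode <- data.frame(
    mode = as.integer(sub("^a", "", modes[keep])),
    mean = mu, sd = sdev, margin = margin,
    one_sided_fraction = osf, sustained = sustained,
    row.names = NULL)
  list(sustained = any(sustained), per_mode = per_mode,
       n_frames = nrow(amps))
}
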