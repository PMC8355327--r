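#' Default open active contour parameters
#'
#' Parameters of the open-snake contour tracker.  `alpha` penalises
#' stretching (first differences), `beta` penalises bending (second
#' differences), `kappa` scales the external ridge-attraction force (the
#' gradient of the Gaussian-smoothed image, normalised to unit maximum
#' magnitude), `gamma` is the implicit-step damping, `stretch` scales the
#' outward tangential force on the two endpoints (proportional to the
#' local normalised intensity, so ends extend along a bright ridge and
#' stop beyond its tip, balancing the inward pull of the intensity
#' gradient), `smooth_sigma` the
#' image smoothing scale in pixels, `ds` the arclength resampling step in
#' pixels, `tol` the convergence tolerance on the maximum point displacement
#' per iteration, and `length_guard` the maximum tolerated fractional
#' frame-to-frame contour length change before a frame is re-evolved and
#' flagged.  Defaults were tuned on rendered synthetic tubules.
#'
#' @param ... overrides of the defaults.
#' @return Named list of parameters.
#' @export
snake_params <- function(...) {
  p <- list(alpha = 0.05, beta = 0.5, kappa = 2, gamma = 1,
            stretch = 2.5, smooth_sigma = 1, ds = 1, tol = 0.01,
            max_iter = 500L, length_guard = 0.2)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown snake parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

# Gaussian smoothing of an image via FFT (periodic edges are acceptable for
# the interior-placed filaments this tracker is used on).
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  fr <- ifelse(seq_len(nr) - 1 <= nr %/% 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr) / nr
  fc <- ifelse(seq_len(nc) - 1 <= nc %/% 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc) / nc
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  Re(fft(fft(image) * H, inverse = TRUE)) / (nr * nc)
}

# External force field: normalised gradient of the smoothed image.
# Returns a list of two matrices (fx, fy).
snake_force_field <- function(image, sigma) {
  sm <- gaussian_smooth(image, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  mx <- max(sqrt(gx^2 + gy^2))
  if (mx > 0) { gx <- gx / mx; gy <- gy / mx }
  rng <- range(sm)
  inten <- if (diff(rng) > 0) (sm - rng[1L]) / diff(rng) else sm * 0
  list(fx = gx, fy = gy, intensity = inten)
}

# drop consecutive near-duplicate points (can arise from clamping at the
# image border); the snake needs strictly distinct consecutive points
drop_duplicate_points <- function(p, tol = 1e-9) {
  if (nrow(p) < 2L) return(p)
  keep <- c(TRUE, rowSums(diff(p)^2) > tol^2)
  p[keep, , drop = FALSE]
}

# Internal-energy matrix for an open snake with K points.
snake_internal_matrix <- function(K, alpha, beta) {
  D1 <- diff(diag(K))
  A <- alpha * crossprod(D1)
  if (K >= 3L) {
    D2 <- diff(diag(K), differences = 2L)
    A <- A + beta * crossprod(D2)
  }
  A
}

#' Evolve an open active contour onto image features
#'
#' Iteratively deforms an open contour under internal elasticity and
#' stiffness forces and an external ridge-attraction force (the gradient of
#' the Gaussian-smoothed image), so that the contour settles on the bright
#' ridge of a tubule.  Endpoints are free and feel the external force.  The
#' contour is resampled to a fixed arclength step after every iteration;
#' iteration stops when the maximum point displacement falls below `tol` or
#' `max_iter` is reached.
#'
#' @param image numeric matrix (already preprocessed).
#' @param initial_contour a [filament_contour()] inside the image.
#' @param params parameter list from [snake_params()].
#' @return Converged [filament_contour()] with attributes `iterations` and
#'   `converged`.
#' @export
evolve_open_contour <- function(image, initial_contour,
                                params = snake_params()) {
  stopifnot(is.matrix(image), inherits(initial_contour, "filament_contour"))
  ff <- snake_force_field(image, params$smooth_sigma)
  p <- initial_contour$points
  contour <- resample_contour(initial_contour,
                              max(3L, round(initial_contour$length_px /
                                              params$ds) + 1L))
  p <- contour$points
  nr <- nrow(image); nc <- ncol(image)
  B <- NULL; lastK <- -1L
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$max_iter)) {
    K <- nrow(p)
    if (K < 3L) stop("contour collapsed to fewer than 3 points")
    if (K != lastK) {
      B <- params$gamma * diag(K) +
        snake_internal_matrix(K, params$alpha, params$beta)
      Mint <- solve(B[2:(K - 1L), 2:(K - 1L)])
      lastK <- K
    }
    fx <- params$kappa * bicubic_interp(ff$fx, p[, 1L], p[, 2L])
    fy <- params$kappa * bicubic_interp(ff$fy, p[, 1L], p[, 2L])
    # endpoints follow the external force plus an outward tangential
    # stretching force gated by local intensity: internal elasticity must
    # not drag the free ends inward (open snakes contract otherwise), and
    # the stretch keeps ends at the ridge tip instead of sliding inward
    t1 <- p[1L, ] - p[2L, ]; t1 <- t1 / sqrt(sum(t1^2))
    tK <- p[K, ] - p[K - 1L, ]; tK <- tK / sqrt(sum(tK^2))
    i1 <- bicubic_interp(ff$intensity, p[1L, 1L], p[1L, 2L])
    iK <- bicubic_interp(ff$intensity, p[K, 1L], p[K, 2L])
    e1 <- p[1L, ] + (c(fx[1L], fy[1L]) + params$stretch * i1 * t1) /
      params$gamma
    eK <- p[K, ] + (c(fx[K], fy[K]) + params$stretch * iK * tK) /
      params$gamma
    idx <- 2:(K - 1L)
    rhsx <- params$gamma * p[idx, 1L] + fx[idx] -
      B[idx, 1L] * e1[1L] - B[idx, K] * eK[1L]
    rhsy <- params$gamma * p[idx, 2L] + fy[idx] -
      B[idx, 1L] * e1[2L] - B[idx, K] * eK[2L]
    newx <- c(e1[1L], Mint %*% rhsx, eK[1L])
    newy <- c(e1[2L], Mint %*% rhsy, eK[2L])
    newx <- pmin(pmax(newx, 0), nc - 1)
    newy <- pmin(pmax(newy, 0), nr - 1)
    shift <- max(sqrt((newx - p[, 1L])^2 + (newy - p[, 2L])^2))
    p <- drop_duplicate_points(cbind(newx, newy))
    if (nrow(p) < 3L) stop("contour collapsed to fewer than 3 points")
    # resample only when the spacing has drifted: repeated linear
    # resampling cuts corners and would erode genuine curvature
    seg <- sqrt(rowSums(diff(p)^2))
    if (max(seg) > 1.5 * params$ds || min(seg) < 0.5 * params$ds) {
      ctr <- filament_contour(p, pixel_size = initial_contour$pixel_size,
                              frame_index = initial_contour$frame_index)
      ctr <- resample_contour(ctr, max(3L, round(ctr$length_px /
                                                   params$ds) + 1L))
      p <- ctr$points
    }
    if (shift < params$tol) { converged <- TRUE; break }
  }
  out <- filament_contour(p, pixel_size = initial_contour$pixel_size,
                          frame_index = initial_contour$frame_index)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Contour time series
#'
#' Per-frame contours of one tubule, resampled to a common number of
#' backbone points so that fractional-arclength point correspondence holds
#' across frames.
#'
#' @param contours list of [filament_contour()], all with the same number of
#'   points.
#' @param times frame times in seconds.
#' @param flags logical vector, TRUE for frames where tracking was degraded
#'   (length-jump guard fired).
#' @param params tracker parameters used (provenance).
#' @return Object of class `contour_series`.
#' @export
contour_series <- function(contours, times = seq_along(contours) - 1,
                           flags = logical(length(contours)),
                           params = NULL) {
  ks <- vapply(contours, function(ct) nrow(ct$points), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all contours in a series must have the same number of points")
  if (length(times) != length(contours))
    stop("times and contours differ in length")
  structure(list(contours = contours, times = as.numeric(times),
                 flags = flags, params = params,
                 pixel_size = contours[[1L]]$pixel_size),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour_series> %d frames x %d points (%d flagged)\n",
              length(x$contours), nrow(x$contours[[1L]]$points),
              sum(x$flags)))
  invisible(x)
}

#' @export
length.contour_series <- function(x) length(x$contours)

#' Track a tubule contour through a video
#'
#' Evolves an open active contour in every frame.  The user supplies the
#' tubule endpoints in the first frame only; each subsequent frame is
#' initialised from the converged contour of the previous frame.  If the
#' contour length changes by more than the configured guard fraction
#' between frames the frame is re-evolved from the previous contour with
#' four-fold internal weights; if the jump persists the previous contour is
#' kept and the frame flagged, which suppresses spurious length changes due
#' to tracking errors.
#'
#' @param video 3D numeric array (rows, columns, frames).
#' @param endpoints_frame0 2x2 matrix, rows = tubule endpoints in frame 1,
#'   columns = (x, y) pixels.
#' @param params tracker parameters, see [snake_params()].
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param n_points number of backbone points in the output series; default
#'   from the first-frame contour length and `params$ds`.
#' @return A [contour_series()].  A warning is issued when 20% or more of
#'   frames were flagged.
#' @export
track_contour_video <- function(video, endpoints_frame0,
                                params = snake_params(),
                                pixel_size = 0.104, frame_interval = 0.03,
                                n_points = NULL) {
  stopifnot(length(dim(video)) == 3L)
  n_frames <- dim(video)[3L]
  endpoints_frame0 <- as.matrix(endpoints_frame0)
  init <- filament_contour(endpoints_frame0, pixel_size = pixel_size)
  init <- resample_contour(init, max(3L, round(init$length_px /
                                                 params$ds) + 1L))
  contours <- vector("list", n_frames)
  flags <- logical(n_frames)
  prev <- init
  strong <- params
  strong$alpha <- params$alpha * 4
  strong$beta <- params$beta * 4
  for (f in seq_len(n_frames)) {
    cur <- evolve_open_contour(video[, , f], prev, params)
    if (f > 1L) {
      jump <- abs(cur$length_px - prev$length_px) / prev$length_px
      if (jump > params$length_guard) {
        cur2 <- evolve_open_contour(video[, , f], prev, strong)
        jump2 <- abs(cur2$length_px - prev$length_px) / prev$length_px
        if (jump2 > params$length_guard) {
          cur <- prev                     # revert: keep previous contour
          flags[f] <- TRUE
        } else {
          cur <- cur2
          flags[f] <- TRUE
        }
      }
    }
    cur$frame_index <- f
    contours[[f]] <- cur
    prev <- cur
  }
  if (is.null(n_points))
    n_points <- max(3L, round(stats::median(
      vapply(contours, function(ct) ct$length_px, numeric(1))) /
        params$ds) + 1L)
  contours <- lapply(contours, resample_contour, n_points = n_points)
  if (n_frames > 1L && mean(flags) >= 0.2)
    warning(sprintf("%.0f%% of frames hit the length-jump guard",
                    100 * mean(flags)))
  contour_series(contours, times = (seq_len(n_frames) - 1) * frame_interval,
                 flags = flags, params = params)
}
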