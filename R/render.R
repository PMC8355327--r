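#' Rendering configuration for synthetic tubule videos
#'
#' @param image_size c(rows, columns) in pixels.
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param peak peak intensity of the tubule above background (counts).
#' @param background background level (counts).
#' @param noise noise model: `"none"`, `"gaussian"`, `"poisson"` or
#'   `"both"`.
#' @param gaussian_sd standard deviation of the Gaussian read noise.
#' @param pixel_size micrometres per pixel (metadata).
#' @param seed RNG seed for the noise.
#' @return Named list of class `render_config`.
#' @export
render_config <- function(image_size = c(64L, 64L), psf_sigma = 1.5,
                          peak = 100, background = 10,
                          noise = c("gaussian", "none", "poisson", "both"),
                          gaussian_sd = 2, pixel_size = 0.104, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(image_size) == 2L, psf_sigma > 0, peak > 0,
            background >= 0, gaussian_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 psf_sigma = psf_sigma, peak = peak,
                 background = background, noise = noise,
                 gaussian_sd = gaussian_sd, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "render_config")
}

# draw one filament frame: line source convolved with a Gaussian PSF.
# points are in pixel coordinates (origin at top-left pixel centre).
render_frame <- function(points, config) {
  nr <- config$image_size[1L]; nc <- config$image_size[2L]
  if (any(points[, 1L] < 0) || any(points[, 1L] > nc - 1) ||
      any(points[, 2L] < 0) || any(points[, 2L] > nr - 1))
    stop("filament exits the frame")
  img <- matrix(config$background, nr, nc)
  sigma <- config$psf_sigma
  step <- 0.2                                 # supersampling step, px
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  spos <- seq(0, total, by = step)
  xs <- stats::approx(cum, points[, 1L], xout = spos, ties = "ordered")$y
  ys <- stats::approx(cum, points[, 2L], xout = spos, ties = "ordered")$y
  # line density such that the cross-section peak equals config$peak
  lambda <- config$peak * sqrt(2 * pi) * sigma
  amp <- lambda * step / (2 * pi * sigma^2)
  half <- ceiling(4 * sigma)
  for (j in seq_along(xs)) {
    cx <- round(xs[j]); cy <- round(ys[j])
    c0 <- max(0L, cx - half); c1 <- min(nc - 1L, cx + half)
    r0 <- max(0L, cy - half); r1 <- min(nr - 1L, cy + half)
    px <- c0:c1; py <- r0:r1
    g <- amp * outer(exp(-(py - ys[j])^2 / (2 * sigma^2)),
                     exp(-(px - xs[j])^2 / (2 * sigma^2)))
    img[py + 1L, px + 1L] <- img[py + 1L, px + 1L] + g
  }
  img
}

#' Render a filament series as a noisy microscopy-like video
#'
#' Each frame draws the filament as a line source convolved with a
#' Gaussian point-spread function on a constant background, then applies
#' the configured noise (Poisson shot noise on the counts and/or additive
#' Gaussian read noise).  The input ground-truth coordinates are returned
#' alongside.
#'
#' @param truth a [contour_series()] with contours in pixel coordinates.
#' @param config a [render_config()].
#' @return List with `video` (rows x columns x frames array), `truth`
#'   (the input series), and `config`.
#' @export
render_video <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "contour_series"))
  set.seed(config$seed)
  n_frames <- length(truth$contours)
  video <- array(0, c(config$image_size, n_frames))
  for (f in seq_len(n_frames)) {
    img <- render_frame(truth$contours[[f]]$points, config)
    if (config$noise %in% c("poisson", "both"))
      img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
    if (config$noise %in% c("gaussian", "both"))
      img <- img + rnorm(length(img), 0, config$gaussian_sd)
    video[, , f] <- img
  }
  list(video = video, truth = truth, config = config)
}

#' Write a video array as a multi-frame grayscale TIFF
#'
#' Intensities are stored as 32-bit floats scaled to \code{[0, 1]} by
#' `scale` (default: the video maximum); the scale is returned so the
#' original counts can be restored on reading.
#'
#' @param video 3D numeric array (rows, columns, frames).
#' @param path output file.
#' @param scale divisor applied before writing; default `max(video)`.
#' @return `scale`, invisibly.
#' @export
write_video_tiff <- function(video, path, scale = NULL) {
  stopifnot(length(dim(video)) == 3L)
  if (is.null(scale)) scale <- max(video, 1e-12)
  frames <- lapply(seq_len(dim(video)[3L]), function(f)
    pmin(pmax(video[, , f] / scale, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Read a multi-frame grayscale TIFF as a video array
#'
#' @param path TIFF file.
#' @param scale multiplier applied after reading (inverse of the scale
#'   used by [write_video_tiff()]).
#' @return 3D numeric array (rows, columns, frames).
#' @export
read_video_tiff <- function(path, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(fr) {
    if (length(dim(fr)) == 3L) fr <- fr[, , 1L]
    fr
  })
  array(unlist(frames), c(dim(frames[[1L]]), length(frames))) * scale
}
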