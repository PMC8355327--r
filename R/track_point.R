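#' Fourier band-pass filter for a grayscale frame
#'
#' Gaussian band-pass in the frequency domain: structures smaller than
#' `small` pixels and larger than `large` pixels are suppressed, which
#' highlights tubule-scale features before tracking.
#'
#' @param image numeric matrix.
#' @param small low-pass scale in pixels (suppresses finer structure).
#' @param large high-pass scale in pixels (suppresses coarser structure).
#' @return Filtered matrix of the same size.
#' @export
bandpass_filter <- function(image, small = 1, large = 10) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  fr <- ifelse(seq_len(nr) - 1 <= nr %/% 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr) / nr
  fc <- ifelse(seq_len(nc) - 1 <= nc %/% 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc) / nc
  r2 <- outer(fr^2, fc^2, "+")
  H <- exp(-2 * pi^2 * small^2 * r2) *
    (1 - exp(-2 * pi^2 * large^2 * r2))
  Re(fft(fft(image) * H, inverse = TRUE)) / (nr * nc)
}

#' Rolling-ball style background subtraction
#'
#' Estimates the background as a grayscale morphological opening with a disc
#' structuring element of the given radius and subtracts it, clamping at
#' zero.
#'
#' @param image numeric matrix.
#' @param radius ball radius in pixels.
#' @return Background-subtracted matrix.
#' @export
subtract_background <- function(image, radius = 50) {
  stopifnot(is.matrix(image))
  size <- 2L * as.integer(radius) + 1L
  cap <- min(dim(image))
  if (size > cap) size <- if (cap %% 2L == 0L) cap - 1L else cap
  if (size < 3L) return(image)
  lo <- min(image)
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(image - lo, brush)) + lo
  pmax(image - bg, 0)
}

#' Preprocess a video for tubule tracking
#'
#' Applies the band-pass filter and rolling-ball background subtraction to
#' every frame.
#'
#' @param video 3D numeric array (rows, columns, frames).
#' @param small,large band-pass scales in pixels, see [bandpass_filter()].
#' @param rolling_radius rolling-ball radius in pixels.
#' @return Preprocessed array of the same dimensions.
#' @export
preprocess_video <- function(video, small = 1, large = 10,
                             rolling_radius = 50) {
  stopifnot(length(dim(video)) == 3L)
  out <- video
  for (f in seq_len(dim(video)[3L])) {
    fr <- bandpass_filter(video[, , f], small = small, large = large)
    out[, , f] <- subtract_background(fr, radius = rolling_radius)
  }
  out
}

#' Tracked point series
#'
#' Per-frame sub-pixel position of one point on a tubule.
#'
#' @param data data frame with columns `frame`, `t` (s), `position_px`
#'   (scalar position along the tracking line), `x`, `y` (image
#'   coordinates, pixels), `valid`, `snr`.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param line_endpoints optional 2x2 matrix of the tracking line.
#' @return An object of class `tracked_points` (a data frame with
#'   attributes).
#' @export
tracked_points <- function(data, pixel_size = 1, frame_interval = 1,
                           line_endpoints = NULL) {
  need <- c("frame", "t", "position_px", "x", "y", "valid", "snr")
  if (!all(need %in% names(data)))
    stop("tracked point data must have columns: ",
         paste(need, collapse = ", "))
  if (any(diff(data$t) <= 0)) stop("frame times must be strictly increasing")
  data$x[!data$valid] <- NA_real_
  data$y[!data$valid] <- NA_real_
  data$position_px[!data$valid] <- NA_real_
  structure(data, pixel_size = pixel_size, frame_interval = frame_interval,
            line_endpoints = line_endpoints,
            class = c("tracked_points", "data.frame"))
}

#' @export
print.tracked_points <- function(x, ...) {
  cat(sprintf(
    "<tracked_points> %d frames (%d valid), dt = %g s, pixel = %g um\n",
    nrow(x), sum(x$valid), attr(x, "frame_interval"),
    attr(x, "pixel_size")))
  invisible(x)
}

#' Track a tubule position along a fixed line through a video
#'
#' For each frame: extract the intensity profile along the line by bicubic
#' interpolation, upsample it to 100 values by kriging, gate on
#' signal-to-noise ratio, and fit a Gaussian with offset by robust
#' (Cauchy-weighted) nonlinear regression.  The fitted Gaussian centre is
#' the tubule position on the line.  Frames failing the gate or the fit are
#' flagged invalid and carry no position.  Frames are preprocessed first
#' (Fourier band-pass plus rolling-ball background subtraction) unless
#' `preprocess = FALSE`.
#'
#' @param video 3D numeric array (rows, columns, frames), >= 10 frames.
#' @param line_endpoints 2x2 matrix, rows = endpoints, columns = (x, y) in
#'   pixels; the line is fixed across frames.
#' @param snr_threshold SNR gate threshold (see
#'   [calibrate_snr_threshold()]).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param n_samples raw profile samples; default one per pixel of line
#'   length (at least 8).
#' @param n_out kriging-upsampled profile length.
#' @param preprocess apply [preprocess_video()] first.
#' @param small,large,rolling_radius preprocessing parameters.
#' @return A [tracked_points()] series.  If more than half of the frames
#'   are invalid a warning is attached (attribute `warning`).
#' @export
track_point <- function(video, line_endpoints, snr_threshold,
                        pixel_size = 0.104, frame_interval = 0.03,
                        n_samples = NULL, n_out = 100L,
                        preprocess = TRUE, small = 1, large = 10,
                        rolling_radius = 50) {
  stopifnot(length(dim(video)) == 3L)
  n_frames <- dim(video)[3L]
  if (n_frames < 10L) stop("need at least 10 frames")
  line_endpoints <- as.matrix(line_endpoints)
  if (preprocess)
    video <- preprocess_video(video, small = small, large = large,
                              rolling_radius = rolling_radius)
  len <- sqrt(sum((line_endpoints[2L, ] - line_endpoints[1L, ])^2))
  if (is.null(n_samples)) n_samples <- max(8L, ceiling(len) + 1L)
  p0 <- line_endpoints[1L, ]
  dir <- (line_endpoints[2L, ] - p0) / len
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pos <- NA_real_; ok <- FALSE; snr <- NA_real_
    prof <- tryCatch(extract_profile(video[, , f], line_endpoints,
                                     n_samples = n_samples),
                     error = function(e) NULL)
    if (!is.null(prof)) {
      up <- tryCatch(krig_upsample(prof, n_out = n_out),
                     error = function(e) NULL)
      if (!is.null(up)) {
        gate <- snr_gate(up, threshold = snr_threshold)
        snr <- gate$snr
        if (gate$pass) {
          ctr <- fit_center(up)
          if (ctr$converged && !ctr$flagged &&
              is.finite(ctr$center) && ctr$center >= 0 &&
              ctr$center <= len) {
            pos <- ctr$center; ok <- TRUE
          }
        }
      }
    }
    rows[[f]] <- data.frame(
      frame = f, t = (f - 1) * frame_interval, position_px = pos,
      x = p0[1L] + if (ok) pos * dir[1L] else NA_real_,
      y = p0[2L] + if (ok) pos * dir[2L] else NA_real_,
      valid = ok, snr = snr)
  }
  out <- tracked_points(do.call(rbind, rows), pixel_size = pixel_size,
                        frame_interval = frame_interval,
                        line_endpoints = line_endpoints)
  if (mean(out$valid) < 0.5) {
    warning("more than 50% of frames failed tracking")
    attr(out, "warning") <- "more than 50% of frames invalid"
  }
  out
}
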