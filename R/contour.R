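#' Filament contour
#'
#' An ordered set of 2D points tracing one tubule (or any filament) in a
#' single frame.  Points are in pixel units; `pixel_size` converts lengths to
#' micrometres at reporting time.
#'
#' @param points two-column numeric matrix (x, y) in pixels, at least 2 rows;
#'   consecutive points must be distinct.
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param frame_index integer frame number the contour belongs to.
#' @return An object of class `filament_contour`: a list with elements
#'   `points`, `pixel_size`, `frame_index` and derived arclength bookkeeping
#'   `ds` (segment lengths, pixels), `s` (segment arclength midpoints,
#'   pixels) and `length_px` (total contour length, pixels).
#' @examples
#' fc <- filament_contour(cbind(c(0, 3), c(0, 4)))
#' contour_length(fc)  # 5 pixels * pixel_size
#' @seealso [contour_length()], [end_to_end()], [resample_contour()]
#' @export
filament_contour <- function(points, pixel_size = 1, frame_index = 1L) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("'points' must be a two-column numeric matrix")
  if (nrow(points) < 2L)
    stop("a filament contour needs at least 2 points")
  if (any(!is.finite(points)))
    stop("contour points must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  dimnames(points) <- list(NULL, c("x", "y"))
  ds <- sqrt(rowSums(diff(points)^2))
  if (any(ds == 0))
    stop("repeated identical consecutive points in contour")
  s <- cumsum(ds) - ds / 2
  structure(
    list(points = points, pixel_size = pixel_size,
         frame_index = as.integer(frame_index),
         ds = ds, s = s, length_px = sum(ds)),
    class = "filament_contour")
}

#' @export
print.filament_contour <- function(x, ...) {
  cat(sprintf(
    "<filament_contour> %d points, L = %.3f um (%.2f px), R = %.3f um, frame %d\n",
    nrow(x$points), contour_length(x), x$length_px, end_to_end(x),
    x$frame_index))
  invisible(x)
}

#' Contour length of a filament
#'
#' Sum of Euclidean segment lengths along the contour, converted to
#' micrometres via the stored pixel size.
#'
#' @param contour a [filament_contour()].
#' @return Length in micrometres.
#' @export
contour_length <- function(contour) {
  stopifnot(inherits(contour, "filament_contour"))
  contour$length_px * contour$pixel_size
}

#' End-to-end distance of a filament
#'
#' Straight-line distance between the first and last contour points, in
#' micrometres.
#'
#' @param contour a [filament_contour()].
#' @return Distance in micrometres.
#' @export
end_to_end <- function(contour) {
  stopifnot(inherits(contour, "filament_contour"))
  p <- contour$points
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2)) * contour$pixel_size
}

#' Resample a contour to equally spaced arclength points
#'
#' Linear interpolation along the polyline at `n_points` positions with equal
#' arclength spacing (endpoints preserved).  Used to establish point
#' correspondence across frames.
#'
#' @param contour a [filament_contour()].
#' @param n_points number of output points (>= 2).
#' @return A new [filament_contour()] with `n_points` points.
#' @export
resample_contour <- function(contour, n_points) {
  stopifnot(inherits(contour, "filament_contour"), n_points >= 2)
  p <- contour$points
  cum <- c(0, cumsum(contour$ds))
  target <- seq(0, cum[length(cum)], length.out = n_points)
  x <- stats::approx(cum, p[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(cum, p[, 2L], xout = target, ties = "ordered")$y
  filament_contour(cbind(x, y), pixel_size = contour$pixel_size,
                   frame_index = contour$frame_index)
}
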