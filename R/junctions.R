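#' Find tubule ends belonging to each junction
#'
#' A tubule end (first or last contour point) is a member of a junction if it
#' lies within `radius` pixels of the junction position.  The coordination
#' number of a junction is its number of member ends.  Junctions with fewer
#' than two members are flagged and excluded from angle analysis.
#'
#' @param graph a [network_graph()].
#' @param radius junction search radius in pixels (default 2).
#' @return A list with one element per junction, each a list with
#'   `position`, `members` (data frame: `tubule`, `end` ("start"/"end"),
#'   `distance`), `coordination`, and `valid` (TRUE iff >= 2 members).
#' @export
find_junction_members <- function(graph, radius = 2) {
  stopifnot(inherits(graph, "network_graph"))
  if (nrow(graph$junctions) == 0L) return(list())
  ends <- do.call(rbind, lapply(seq_along(graph$tubules), function(i) {
    p <- graph$tubules[[i]]$points
    rbind(c(i, 1, p[1L, ]), c(i, 2, p[nrow(p), ]))
  }))
  lapply(seq_len(nrow(graph$junctions)), function(j) {
    pos <- graph$junctions[j, ]
    d <- sqrt((ends[, 3L] - pos[1L])^2 + (ends[, 4L] - pos[2L])^2)
    sel <- which(d <= radius)
    members <- data.frame(
      tubule = as.integer(ends[sel, 1L]),
      end = c("start", "end")[ends[sel, 2L]],
      distance = d[sel])
    list(position = pos, members = members,
         coordination = length(sel), valid = length(sel) >= 2L)
  })
}

# Direction of the ray leaving a junction along one member tubule end.
# Orthogonal (total) least squares through the n_fit points nearest the
# junction end; sign oriented away from the junction.  Returns a unit vector
# or NULL when the points are degenerate (all coincident).
member_direction <- function(contour, end, n_fit = 5L) {
  p <- contour$points
  n <- nrow(p)
  k <- min(n_fit, n)
  pts <- if (end == "start") p[seq_len(k), , drop = FALSE]
         else p[seq(n, n - k + 1L), , drop = FALSE]
  centred <- sweep(pts, 2L, colMeans(pts))
  if (all(abs(centred) < 1e-12)) return(NULL)
  v <- svd(centred, nu = 0L, nv = 1L)$v[, 1L]
  # orient from the junction-side endpoint toward the far end of the fit span
  along <- pts[nrow(pts), ] - pts[1L, ]
  if (sum(v * along) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Angles between tubules at a junction
#'
#' Each member tubule end contributes a direction obtained from a
#' least-squares line through the 5 contour points closest to the junction
#' (all points when the tubule has fewer than 5), oriented away from the
#' junction.  For a 2-way junction the single smallest angle between the two
#' rays is returned, in (0, 180] degrees.  For n-way junctions (n >= 3) the
#' adjacent angles between azimuthally ordered rays are returned (they sum
#' to 360 degrees).
#'
#' @param graph a [network_graph()].
#' @param junction one element of [find_junction_members()] output, or the
#'   junction index.
#' @param radius junction search radius in pixels, used when `junction` is
#'   given as an index.
#' @param n_fit number of contour points used for each direction fit.
#' @return Numeric vector of angles in degrees.
#' @export
junction_angles <- function(graph, junction, radius = 2, n_fit = 5L) {
  stopifnot(inherits(graph, "network_graph"))
  if (is.numeric(junction)) {
    junction <- find_junction_members(graph, radius = radius)[[junction]]
  }
  if (!isTRUE(junction$valid))
    stop("junction has fewer than 2 member tubule ends")
  dirs <- list()
  for (m in seq_len(nrow(junction$members))) {
    tub <- graph$tubules[[junction$members$tubule[m]]]
    v <- member_direction(tub, junction$members$end[m], n_fit = n_fit)
    if (is.null(v)) {
      warning("degenerate direction fit at junction member skipped")
      next
    }
    dirs[[length(dirs) + 1L]] <- v
  }
  if (length(dirs) < 2L)
    stop("fewer than 2 usable member directions at junction")
  az <- vapply(dirs, function(v) atan2(v[2L], v[1L]), numeric(1))
  if (length(dirs) == 2L) {
    ang <- abs(az[1L] - az[2L]) %% (2 * pi)
    ang <- min(ang, 2 * pi - ang) * 180 / pi
    return(ang)
  }
  az <- sort(az)
  gaps <- diff(c(az, az[1L] + 2 * pi))
  gaps * 180 / pi
}

#' Coordination-number summary of a network
#'
#' Fraction of junctions with each coordination number (number of tubule ends
#' within the junction search radius).  Junctions with fewer than 2 members
#' are excluded.  Coordination numbers of 5 or more are reported but are
#' expected to be rare in ER networks.
#'
#' @param graph a [network_graph()].
#' @param radius junction search radius in pixels.
#' @return Named numeric vector of fractions (names = coordination numbers),
#'   summing to 1, with attribute `counts`.
#' @export
coordination_summary <- function(graph, radius = 2) {
  mem <- find_junction_members(graph, radius = radius)
  if (length(mem) == 0L) stop("network has no junctions")
  coord <- vapply(mem, `[[`, numeric(1), "coordination")
  coord <- coord[coord >= 2L]
  if (length(coord) == 0L) stop("no junction has >= 2 member tubule ends")
  tab <- table(coord)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  attr(out, "counts") <- as.integer(tab)
  out
}

#' Per-tubule length table for a network
#'
#' @param graph a [network_graph()].
#' @return Data frame with `tubule`, `L_um` (contour length) and `R_um`
#'   (end-to-end distance) in micrometres.
#' @export
tubule_lengths <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  data.frame(
    tubule = seq_along(graph$tubules),
    L_um = vapply(graph$tubules, contour_length, numeric(1)),
    R_um = vapply(graph$tubules, end_to_end, numeric(1)))
}
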