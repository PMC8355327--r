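#' Network graph of traced tubules and junctions
#'
#' Container for a traced filament network: a list of tubule contours plus
#' junction positions, as produced by snake-based network tracing of a still
#' image.
#'
#' @param tubules list of [filament_contour()] objects.
#' @param junctions two-column numeric matrix (x, y) of junction positions in
#'   pixels; may have zero rows.
#' @param pixel_size micrometres per pixel, propagated to reporting.
#' @return An object of class `network_graph`.
#' @export
network_graph <- function(tubules, junctions = NULL, pixel_size = 1) {
  if (!is.list(tubules) || length(tubules) == 0L)
    stop("'tubules' must be a non-empty list of filament_contour objects")
  ok <- vapply(tubules, inherits, logical(1), "filament_contour")
  if (!all(ok))
    stop("all elements of 'tubules' must be filament_contour objects")
  if (is.null(junctions)) {
    junctions <- matrix(numeric(0), ncol = 2L)
  } else {
    junctions <- as.matrix(junctions)
    if (ncol(junctions) != 2L)
      stop("'junctions' must be a two-column (x, y) matrix")
  }
  dimnames(junctions) <- list(NULL, c("x", "y"))
  structure(list(tubules = tubules, junctions = junctions,
                 pixel_size = pixel_size),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d tubules, %d junctions\n",
              length(x$tubules), nrow(x$junctions)))
  invisible(x)
}

#' Read a SOAX snake text file
#'
#' Parses the text output of SOAX network tracing: snakes introduced by
#' `#<id>` lines followed by point records
#' `snake_index point_index x y z [intensity]`, and an optional junction
#' section opened by a line beginning with `[`, with one `x y z` row per
#' junction.  Parameter header lines before the first snake are ignored.
#'
#' @param file path to a SOAX output text file.
#' @param pixel_size micrometres per pixel for the traced image.
#' @return A [network_graph()] with one [filament_contour()] per snake
#'   (coordinates in pixels) and the junction positions.
#' @export
read_soax <- function(file, pixel_size = 1) {
  lines <- readLines(file, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(trimws(lines) == ""))
    stop("empty SOAX file: ", file)
  snakes <- list()
  current <- NULL
  junctions <- list()
  in_junctions <- FALSE
  seen_snake <- FALSE
  flush_snake <- function() {
    if (is.null(current) || length(current) == 0L) return()
    pts <- do.call(rbind, current)
    if (nrow(pts) < 2L)
      stop("snake with fewer than 2 points in ", file)
    snakes[[length(snakes) + 1L]] <<- filament_contour(
      pts, pixel_size = pixel_size)
    current <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "[")) {            # junction section
      flush_snake()
      in_junctions <- TRUE
      next
    }
    if (startsWith(ln, "#")) {            # new snake
      flush_snake()
      seen_snake <- TRUE
      current <- list()
      next
    }
    fields <- strsplit(ln, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (in_junctions) {
      if (length(vals) < 2L || any(is.na(vals[1:2])))
        stop(sprintf("malformed junction record at line %d of %s", i, file))
      junctions[[length(junctions) + 1L]] <- vals[1:2]
      next
    }
    if (!seen_snake) next                 # parameter header
    if (length(vals) < 4L || any(is.na(vals)))
      stop(sprintf("malformed snake record at line %d of %s", i, file))
    current[[length(current) + 1L]] <- vals[3:4]
  }
  flush_snake()
  if (length(snakes) == 0L)
    stop("no snakes found in ", file)
  jx <- if (length(junctions)) do.call(rbind, junctions) else NULL
  network_graph(snakes, jx, pixel_size = pixel_size)
}

#' Write a network graph in SOAX snake text format
#'
#' Inverse of [read_soax()]; the written file round-trips through
#' [read_soax()] to an identical internal representation.
#'
#' @param graph a [network_graph()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_soax <- function(graph, file) {
  stopifnot(inherits(graph, "network_graph"))
  con <- file(file, "w")
  on.exit(close(con))
  for (si in seq_along(graph$tubules)) {
    writeLines(sprintf("#%d", si), con)
    p <- graph$tubules[[si]]$points
    writeLines(sprintf("%d\t%d\t%.10g\t%.10g\t0", si, seq_len(nrow(p)) - 1L,
                       p[, 1L], p[, 2L]), con)
  }
  writeLines("[Junctions]", con)
  if (nrow(graph$junctions) > 0L)
    writeLines(sprintf("%.10g\t%.10g\t0", graph$junctions[, 1L],
                       graph$junctions[, 2L]), con)
  invisible(file)
}
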