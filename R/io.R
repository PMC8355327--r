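#' Write network morphometrics results to files
#'
#' Writes a per-tubule CSV (`tubules.csv`: tubule, L_um, R_um), a
#' per-junction CSV (`junctions.csv`: junction, coordination, angles in
#' degrees separated by `;`), and a JSON summary
#' (`network_summary.json`: coordination proportions and, when requested,
#' the persistence-length fit).
#'
#' @param graph a [network_graph()].
#' @param dir output directory (created if needed).
#' @param radius junction search radius, pixels.
#' @param fit_lp also fit and report the persistence length.
#' @return Invisibly, the list of written paths.
#' @export
write_network_results <- function(graph, dir, radius = 2, fit_lp = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tl <- tubule_lengths(graph)
  p_tub <- file.path(dir, "tubules.csv")
  write.csv(tl, p_tub, row.names = FALSE)
  mem <- find_junction_members(graph, radius = radius)
  jrows <- lapply(seq_along(mem), function(j) {
    ang <- if (mem[[j]]$valid)
      tryCatch(junction_angles(graph, mem[[j]], radius = radius),
               error = function(e) numeric(0)) else numeric(0)
    data.frame(junction = j, coordination = mem[[j]]$coordination,
               angles_deg = paste(sprintf("%.4f", ang), collapse = ";"))
  })
  p_jun <- file.path(dir, "junctions.csv")
  write.csv(do.call(rbind, jrows), p_jun, row.names = FALSE)
  summ <- list()
  if (length(mem) > 0L && any(vapply(mem, `[[`, logical(1), "valid")))
    summ$coordination_proportions <- as.list(coordination_summary(
      graph, radius = radius))
  if (fit_lp && nrow(tl) >= 3L) {
    pf <- tryCatch(fit_persistence_length(tl), error = function(e) NULL)
    if (!is.null(pf))
      summ$persistence_fit <- list(Lp_um = pf$Lp, Lp_stderr_um = pf$Lp_stderr,
                                   n_tubules = pf$n_tubules,
                                   near_rigid = pf$near_rigid)
  }
  p_sum <- file.path(dir, "network_summary.json")
  jsonlite::write_json(summ, p_sum, auto_unbox = TRUE, digits = NA)
  invisible(list(tubules = p_tub, junctions = p_jun, summary = p_sum))
}

#' Write a tracked point series as CSV
#'
#' Columns: frame, t, position_px, x, y, valid, snr.
#'
#' @param track a [tracked_points()] series.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read a tracked point series from CSV
#'
#' @param path CSV written by [write_track_csv()].
#' @param pixel_size,frame_interval series metadata (the CSV itself stores
#'   times, so `frame_interval` defaults to the time step found in the
#'   file).
#' @return A [tracked_points()] series.
#' @export
read_track_csv <- function(path, pixel_size = 1, frame_interval = NULL) {
  d <- read.csv(path)
  if (is.null(frame_interval))
    frame_interval <- if (nrow(d) > 1L) diff(d$t)[1L] else 1
  tracked_points(d, pixel_size = pixel_size,
                 frame_interval = frame_interval)
}

#' Write contour series coordinates as CSV
#'
#' One row per (frame, point): tubule, frame, k, x, y.
#'
#' @param series a [contour_series()].
#' @param path output CSV.
#' @param tubule tubule identifier stored in the first column.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(series, path, tubule = 1L) {
  rows <- lapply(seq_along(series$contours), function(f) {
    p <- series$contours[[f]]$points
    data.frame(tubule = tubule, frame = f, k = seq_len(nrow(p)),
               x = p[, 1L], y = p[, 2L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a contour series from CSV
#'
#' @param path CSV written by [write_contour_csv()].
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @return A [contour_series()].
#' @export
read_contour_csv <- function(path, pixel_size = 1, frame_interval = 1) {
  d <- read.csv(path)
  frames <- sort(unique(d$frame))
  contours <- lapply(frames, function(f) {
    sub <- d[d$frame == f, ]
    sub <- sub[order(sub$k), ]
    filament_contour(cbind(sub$x, sub$y), pixel_size = pixel_size,
                     frame_index = f)
  })
  contour_series(contours, times = (frames - min(frames)) * frame_interval)
}

#' Write a run manifest
#'
#' Records inputs, parameters, package version and seed for
#' reproducibility.
#'
#' @param path output JSON file.
#' @param subcommand the stage that ran.
#' @param inputs named list of input paths.
#' @param parameters named list of parameters.
#' @param seed seed used.
#' @param status named list of per-stage status strings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, inputs = list(),
                           parameters = list(), seed = NA_integer_,
                           status = list()) {
  manifest <- list(
    subcommand = subcommand,
    package = "ertrack",
    version = as.character(utils::packageVersion("ertrack")),
    seed = seed, inputs = inputs, parameters = parameters,
    status = status)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a multi-stage run is routed through one master seed;
#' per-stage seeds are derived deterministically from the master seed and
#' the stage name, and stay below 2^31.
#'
#' @param master master seed (integer).
#' @param stage stage name.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
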