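# minimum distance from points (m x 2) to a closed polygon boundary (v x 2)
polygon_boundary_distance <- function(points, poly) {
  poly <- as.matrix(poly)
  a <- poly
  b <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  apply(points, 1L, function(p) {
    t <- ((p[1L] - a[, 1L]) * ab[, 1L] + (p[2L] - a[, 2L]) * ab[, 2L]) /
      pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    qx <- a[, 1L] + t * ab[, 1L]
    qy <- a[, 2L] + t * ab[, 2L]
    sqrt(min((p[1L] - qx)^2 + (p[2L] - qy)^2))
  })
}

# ray-casting point-in-polygon test (even-odd rule)
point_in_polygon <- function(points, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  apply(points, 1L, function(p) {
    crossings <- (poly[, 2L] > p[2L]) != (poly[j, 2L] > p[2L])
    xint <- poly[, 1L] + (p[2L] - poly[, 2L]) /
      (poly[j, 2L] - poly[, 2L]) * (poly[j, 1L] - poly[, 1L])
    sum(crossings & p[1L] < xint) %% 2L == 1L
  })
}

#' Classify a tubule as peripheral or perinuclear
#'
#' For every backbone point the normalised depth between the nuclear
#' envelope and the cell edge is
#' `d = dist(point, nucleus) / (dist(point, nucleus) + dist(point, cell))`,
#' so d = 0 on the nuclear envelope and d = 1 on the cell edge.  A tubule
#' is peripheral when its aggregated depth is at least `threshold`
#' (default 0.9: the outermost 10% of the nucleus-to-edge distance).
#' Aggregation is the mean depth over the backbone by default; `"max"` uses
#' the deepest point instead.
#'
#' @param backbone K x 2 matrix of backbone points (x, y), or a
#'   [filament_contour()] / [compute_backbone_stats()] result.
#' @param nucleus_boundary,cell_boundary closed polygons, v x 2 matrices
#'   (x, y); the nucleus must lie inside the cell.
#' @param threshold peripheral depth cut (default 0.9).
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return List with `peripheral` (logical), `depth` (aggregated), and
#'   `point_depths`.
#' @export
classify_peripheral <- function(backbone, nucleus_boundary, cell_boundary,
                                threshold = 0.9,
                                aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (inherits(backbone, "backbone_stats")) backbone <- backbone$backbone
  if (inherits(backbone, "filament_contour")) backbone <- backbone$points
  backbone <- as.matrix(backbone)
  inside_cell <- point_in_polygon(backbone, cell_boundary)
  if (!all(inside_cell)) stop("backbone point outside the cell boundary")
  in_nucleus <- point_in_polygon(backbone, nucleus_boundary)
  if (any(in_nucleus)) stop("backbone point inside the nucleus")
  dn <- polygon_boundary_distance(backbone, nucleus_boundary)
  dc <- polygon_boundary_distance(backbone, cell_boundary)
  d <- dn / (dn + dc)
  depth <- if (aggregate == "mean") mean(d) else max(d)
  list(peripheral = depth >= threshold, depth = depth, point_depths = d)
}

#' Column order of the tubule property matrix
#'
#' @return Character vector of the 8 fixed column names: presence then
#'   absence of sustained curvature, MSD exponent >= 0.4, peripheral
#'   position, and significant skewness.
#' @export
property_columns <- function() {
  c("curvature", "no_curvature", "msd_high", "msd_low",
    "peripheral", "perinuclear", "skew", "no_skew")
}

#' Build the binary tubule property matrix
#'
#' One row per tubule and 8 binary columns: presence and absence indicators
#' of the four properties in the fixed order of [property_columns()] —
#' sustained curvature, MSD exponent of 0.4 or greater, peripheral
#' position, significant skewness.  For each property exactly one of the
#' two indicator columns is 1 per tubule.  Tubules missing any
#' determination are excluded with a warning.
#'
#' @param results data frame with one row per tubule and columns
#'   `sustained_curvature` (logical), `alpha` (numeric MSD exponent) or
#'   `msd_high` (logical), `peripheral` (logical), `skew` (logical);
#'   optionally `tubule` ids used as row names.
#' @param alpha_cut MSD exponent cut (default 0.4; `alpha >= alpha_cut`
#'   counts as high).
#' @return Binary matrix of class `property_matrix`.
#' @export
build_property_matrix <- function(results, alpha_cut = 0.4) {
  if (!"msd_high" %in% names(results)) {
    if (!"alpha" %in% names(results))
      stop("need either 'msd_high' or 'alpha' in results")
    results$msd_high <- results$alpha >= alpha_cut
  }
  need <- c("sustained_curvature", "msd_high", "peripheral", "skew")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("missing property column(s): ", paste(miss, collapse = ", "))
  ok <- complete.cases(results[need])
  if (!all(ok)) {
    warning(sum(!ok), " tubule(s) with missing determinations excluded")
    results <- results[ok, , drop = FALSE]
  }
  if (nrow(results) == 0L)
    stop("no tubules with complete determinations")
  m <- cbind(
    results$sustained_curvature, !results$sustained_curvature,
    results$msd_high, !results$msd_high,
    results$peripheral, !results$peripheral,
    results$skew, !results$skew) * 1L
  colnames(m) <- property_columns()
  rownames(m) <- if ("tubule" %in% names(results))
    as.character(results$tubule) else NULL
  structure(m, class = c("property_matrix", class(m)))
}

# indices of contradictory column pairs (presence, absence of one property)
contradictory_pairs <- function(n_items) {
  if (n_items %% 2L != 0L) return(matrix(integer(0), ncol = 2L))
  cbind(seq(1L, n_items, by = 2L), seq(2L, n_items, by = 2L))
}

#' Mine association rules from a binary property matrix
#'
#' Exhaustive frequent-itemset search over the (at most 8) items followed
#' by rule generation over every antecedent/consequent bipartition.  For a
#' rule A -> B: support is the fraction of tubules containing all items of
#' A and B; confidence is support(A and B) / support(A); lift is
#' support(A and B) / (support(A) * support(B)).  Itemsets containing both
#' the presence and the absence of the same property are pruned.  Rules are
#' kept when support >= `min_support` and confidence >= `min_confidence`.
#'
#' @param matrix binary matrix (rows = tubules, columns = items), e.g. a
#'   [build_property_matrix()] result, with at least 10 rows.
#' @param min_support minimum rule support in (0, 1] (default 0.1).
#' @param min_confidence minimum rule confidence in (0, 1] (default 0.9).
#' @return Data frame of class `assoc_rules` with columns `antecedent`,
#'   `consequent` (item names joined by " & "), `support`, `confidence`,
#'   `lift`, ordered by decreasing support.
#' @export
mine_rules <- function(matrix, min_support = 0.1, min_confidence = 0.9) {
  m <- unclass(as.matrix(matrix))
  if (!all(m %in% c(0, 1))) stop("property matrix must be binary")
  if (nrow(m) < 10L) stop("rule mining needs at least 10 tubules")
  if (min_support <= 0 || min_support > 1 ||
      min_confidence <= 0 || min_confidence > 1)
    stop("thresholds must lie in (0, 1]")
  n_items <- ncol(m)
  if (n_items > 16L) stop("too many items for exhaustive enumeration")
  items <- colnames(m)
  if (is.null(items)) items <- paste0("item", seq_len(n_items))
  n_rows <- nrow(m)
  masks <- seq_len(2^n_items - 1L)
  # For a property matrix the presence and absence columns of one property
  # are mutually exclusive, so any itemset containing both has support 0;
  # skip counting those (pure optimisation, the counted result is 0 too).
  contradictory <- rep(FALSE, length(masks))
  if (inherits(matrix, "property_matrix")) {
    bad <- contradictory_pairs(n_items)
    for (r in seq_len(nrow(bad))) {
      bits <- bitwOr(bitwShiftL(1L, bad[r, 1L] - 1L),
                     bitwShiftL(1L, bad[r, 2L] - 1L))
      contradictory <- contradictory | (bitwAnd(masks, bits) == bits)
    }
  }
  # support per itemset mask
  support <- rep(NA_real_, length(masks))
  for (mask in masks) {
    if (contradictory[mask]) { support[mask] <- 0; next }
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_items) - 1L)) > 0L)
    support[mask] <- sum(rowSums(m[, cols, drop = FALSE]) ==
                           length(cols)) / n_rows
  }
  frequent <- which(support >= min_support & !contradictory)
  rules <- list()
  for (mask in frequent) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_items) - 1L)) > 0L)
    if (length(cols) < 2L) next
    # every non-empty proper submask as antecedent
    sub <- bitwAnd(masks, mask)
    ants <- unique(sub[sub != 0L & sub != mask])
    for (a in ants) {
      b <- bitwAnd(mask, bitwNot(a))
      conf <- support[mask] / support[a]
      if (conf < min_confidence) next
      lift <- support[mask] / (support[a] * support[b])
      acols <- which(bitwAnd(a, bitwShiftL(1L, seq_len(n_items) - 1L)) > 0L)
      bcols <- which(bitwAnd(b, bitwShiftL(1L, seq_len(n_items) - 1L)) > 0L)
      rules[[length(rules) + 1L]] <- data.frame(
        antecedent = paste(items[acols], collapse = " & "),
        consequent = paste(items[bcols], collapse = " & "),
        support = support[mask], confidence = conf, lift = lift)
    }
  }
  out <- if (length(rules)) do.call(rbind, rules) else
    data.frame(antecedent = character(), consequent = character(),
               support = numeric(), confidence = numeric(),
               lift = numeric())
  out <- out[order(-out$support, out$antecedent, out$consequent), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("assoc_rules", "data.frame"))
}

#' @export
print.assoc_rules <- function(x, digits = 3, ...) {
  cat(sprintf("<assoc_rules> %d rule(s)\n", nrow(x)))
  if (nrow(x)) {
    y <- as.data.frame(x)
    y$support <- signif(y$support, digits)
    y$confidence <- signif(y$confidence, digits)
    y$lift <- signif(y$lift, digits)
    print(y)
  }
  invisible(x)
}
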