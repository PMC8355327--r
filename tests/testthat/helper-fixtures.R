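# shared fixtures built in code

straight_contour <- function(from, to, n = 10L, pixel_size = 1) {
  t <- seq(0, 1, length.out = n)
  filament_contour(cbind(from[1] + t * (to[1] - from[1]),
                         from[2] + t * (to[2] - from[2])),
                   pixel_size = pixel_size)
}

# regular polygon approximating a circle (closed, not repeated first vertex)
circle_poly <- function(center, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# noiseless Gaussian-with-offset profile on a given support
gauss_profile <- function(u, a = 10, b = 100, mu = 5.3, sigma = 1.2) {
  intensity_profile(u, a + b * exp(-(u - mu)^2 / (2 * sigma^2)))
}

# star network: three straight tubules radiating from a common junction
star_graph <- function(center = c(20, 20), angles = c(0, 120, 240) * pi / 180,
                       len = 10, n = 11L) {
  tubules <- lapply(angles, function(a)
    straight_contour(center, center + len * c(cos(a), sin(a)), n = n))
  network_graph(tubules, junctions = rbind(center))
}

# independent brute-force association-rule enumerator: explicit loops over
# item subsets via combn, metrics by direct row counting
brute_force_rules <- function(m, min_support, min_confidence) {
  m <- unclass(as.matrix(m))
  items <- colnames(m)
  n_rows <- nrow(m)
  has_all <- function(cols) {
    cnt <- 0L
    for (r in seq_len(n_rows)) if (all(m[r, cols] == 1)) cnt <- cnt + 1L
    cnt / n_rows
  }
  out <- list()
  idx <- seq_len(ncol(m))
  for (size in 2:length(idx)) {
    sets <- utils::combn(idx, size, simplify = FALSE)
    for (set in sets) {
      s_all <- has_all(set)
      if (s_all < min_support) next
      for (asize in 1:(size - 1L)) {
        ants <- utils::combn(set, asize, simplify = FALSE)
        for (a in ants) {
          b <- setdiff(set, a)
          conf <- s_all / has_all(a)
          if (conf < min_confidence) next
          out[[length(out) + 1L]] <- data.frame(
            antecedent = paste(items[a], collapse = " & "),
            consequent = paste(items[b], collapse = " & "),
            support = s_all, confidence = conf,
            lift = s_all / (has_all(a) * has_all(b)))
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric()))
  res <- do.call(rbind, out)
  res[order(-res$support, res$antecedent, res$consequent), , drop = FALSE]
}

# random but structurally valid property matrix (presence/absence pairs)
random_property_matrix <- function(n_rows, seed) {
  set.seed(seed)
  build_property_matrix(data.frame(
    sustained_curvature = runif(n_rows) < runif(1, 0.2, 0.8),
    msd_high = runif(n_rows) < runif(1, 0.2, 0.8),
    peripheral = runif(n_rows) < runif(1, 0.2, 0.8),
    skew = runif(n_rows) < runif(1, 0.2, 0.8)))
}

# rigid transform of a contour
transform_contour <- function(contour, angle = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  filament_contour(sweep(contour$points %*% t(R), 2L, -shift),
                   pixel_size = contour$pixel_size,
                   frame_index = contour$frame_index)
}
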