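#' Worm-like chain mean square end-to-end distance
#'
#' Kratky-Porod relation for the mean square end-to-end distance of a
#' worm-like chain of contour length `L` and persistence length `Lp`:
#' \deqn{\langle R^2 \rangle = 2 L_p (L - L_p (1 - e^{-L/L_p})).}
#' Limits: `L << Lp` gives `L^2` (rigid rod); `L >> Lp` gives `2 Lp L`
#' (ideal chain).
#'
#' @param L contour length(s), micrometres.
#' @param Lp persistence length, micrometres.
#' @return Mean square end-to-end distance, micrometres squared.
#' @export
wlc_r2 <- function(L, Lp) {
  x <- L / Lp
  # expm1 keeps the small-L limit accurate: R2 -> L^2
  2 * Lp * (L + Lp * expm1(-x))
}

#' Fit the persistence length of a tubule population
#'
#' Nonlinear least-squares fit of the worm-like chain relation [wlc_r2()] to
#' per-tubule (contour length L, squared end-to-end distance R^2) pairs,
#' giving the population persistence length Lp.  By default all pairs enter
#' the fit unbinned; optionally tubules are grouped into equal-count bins of
#' L and the mean R^2 per bin is fitted, as in classic worm-like-chain
#' analyses.
#'
#' @param tubules list of [filament_contour()] objects, or a data frame with
#'   columns `L_um` and `R_um` (as from [tubule_lengths()]).
#' @param bins number of equal-count L bins; `NULL` (default) fits raw pairs.
#' @param start initial Lp guess in micrometres; default `median(L)`.
#' @param lower,upper box bounds for Lp in micrometres.
#' @return Object of class `persistence_fit`: list with `Lp`, `Lp_stderr`,
#'   `residual` (residual sum of squares), `n_tubules`, `near_rigid` flag
#'   (Lp at the upper bound, i.e. data indistinguishable from rigid rods),
#'   `data` (the fitted pairs) and the underlying `nls` fit.
#' @examples
#' L <- seq(0.5, 3, by = 0.5)
#' d <- data.frame(L_um = L, R_um = sqrt(wlc_r2(L, 8.3)))
#' fit_persistence_length(d)
#' @export
fit_persistence_length <- function(tubules, bins = NULL, start = NULL,
                                   lower = 1e-3, upper = 1e4) {
  if (is.data.frame(tubules)) {
    d <- tubules
    if (!all(c("L_um", "R_um") %in% names(d)))
      stop("data frame input needs columns 'L_um' and 'R_um'")
  } else {
    d <- tubule_lengths(network_graph(tubules))
  }
  d <- d[is.finite(d$L_um) & is.finite(d$R_um) & d$L_um > 0, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("persistence-length fit needs at least 3 tubules with valid (L, R)")
  fit_data <- data.frame(L = d$L_um, R2 = d$R_um^2)
  if (!is.null(bins)) {
    bins <- as.integer(bins)
    if (bins < 3L) stop("need at least 3 bins")
    grp <- cut(rank(fit_data$L, ties.method = "first"),
               breaks = bins, labels = FALSE)
    fit_data <- data.frame(
      L = tapply(fit_data$L, grp, mean),
      R2 = tapply(fit_data$R2, grp, mean))
  }
  if (is.null(start)) start <- median(fit_data$L)
  start <- min(max(start, lower), upper)
  fit <- tryCatch(
    minpack.lm::nlsLM(R2 ~ wlc_r2(L, Lp), data = fit_data,
                      start = list(Lp = start),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("persistence-length fit did not converge: ",
                             conditionMessage(e)))
  Lp <- unname(coef(fit)[["Lp"]])
  se <- tryCatch(sqrt(diag(vcov(fit)))[["Lp"]], error = function(e) NA_real_)
  near_rigid <- Lp >= upper * (1 - 1e-6)
  if (near_rigid)
    warning("fitted Lp at upper bound: data are consistent with rigid rods")
  structure(
    list(Lp = Lp, Lp_stderr = unname(se),
         residual = sum(stats::resid(fit)^2),
         n_tubules = nrow(d), near_rigid = near_rigid,
         binned = !is.null(bins), data = fit_data, fit = fit),
    class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("Worm-like chain persistence length fit (%d tubules%s)\n",
              x$n_tubules, if (x$binned) ", binned" else ""))
  cat(sprintf("  Lp = %.4g +/- %.2g um%s\n", x$Lp, x$Lp_stderr,
              if (x$near_rigid) "  [near-rigid: at bound]" else ""))
  invisible(x)
}

#' @export
coef.persistence_fit <- function(object, ...) c(Lp = object$Lp)

#' @export
summary.persistence_fit <- function(object, ...) {
  structure(list(fit = object, nls_summary = summary(object$fit)),
            class = "summary.persistence_fit")
}

#' @export
print.summary.persistence_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sum of squares: %.4g um^4 on %d pairs\n",
              x$fit$residual, nrow(x$fit$data)))
  invisible(x)
}

#' @export
predict.persistence_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else newdata$L
  wlc_r2(L, object$Lp)
}

#' @export
residuals.persistence_fit <- function(object, ...) {
  object$data$R2 - wlc_r2(object$data$L, object$Lp)
}

#' @export
plot.persistence_fit <- function(x, ...) {
  plot(x$data$L, x$data$R2, xlab = "contour length L (um)",
       ylab = expression(R^2 ~ (um^2)), ...)
  Ls <- seq(min(x$data$L), max(x$data$L), length.out = 200)
  lines(Ls, wlc_r2(Ls, x$Lp), col = "red")
  legend("topleft", bty = "n",
         legend = sprintf("Lp = %.3g um", x$Lp), lty = 1, col = "red")
  invisible(x)
}
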