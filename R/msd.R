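#' Time-averaged mean squared displacement of a tracked point
#'
#' Computes the two-dimensional time-averaged MSD
#' \deqn{\langle \Delta r^2(\tau) \rangle =
#'   \langle (x(t+\tau)-x(t))^2 + (y(t+\tau)-y(t))^2 \rangle_t}
#' over all ordered frame pairs at each lag.  Frames flagged invalid are
#' excluded pairwise (never interpolated); lags with fewer than 3
#' contributing pairs are dropped.
#'
#' @param track a [tracked_points()] series with at least 10 valid frames.
#' @param max_lag_fraction largest lag as a fraction of the track length.
#' @return Object of class `msd_result`: data frame with `lag` (frames),
#'   `tau` (s), `msd` (square micrometres) and `n_pairs`, plus attributes
#'   `pixel_size` and `frame_interval`.
#' @export
compute_msd <- function(track, max_lag_fraction = 0.5) {
  stopifnot(inherits(track, "tracked_points"))
  if (sum(track$valid) < 10L)
    stop("MSD needs at least 10 valid frames")
  px <- attr(track, "pixel_size")
  dt <- attr(track, "frame_interval")
  x <- track$x * px; y <- track$y * px
  v <- track$valid
  n <- nrow(track)
  max_lag <- max(1L, floor(n * max_lag_fraction))
  rows <- lapply(seq_len(max_lag), function(lag) {
    i <- seq_len(n - lag)
    keep <- v[i] & v[i + lag]
    if (sum(keep) < 3L) return(NULL)
    dx <- x[i + lag][keep] - x[i][keep]
    dy <- y[i + lag][keep] - y[i][keep]
    data.frame(lag = lag, tau = lag * dt, msd = mean(dx^2 + dy^2),
               n_pairs = sum(keep))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no lag has at least 3 valid pairs")
  out <- do.call(rbind, rows)
  structure(out, pixel_size = px, frame_interval = dt,
            n_frames = n, duration = n * dt,
            class = c("msd_result", "data.frame"))
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d lags, tau in [%g, %g] s\n",
              nrow(x), min(x$tau), max(x$tau)))
  invisible(x)
}

#' @export
plot.msd_result <- function(x, ...) {
  plot(x$tau, x$msd, log = "xy", xlab = expression(tau ~ "(s)"),
       ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Fit a power law to an MSD curve
#'
#' Weighted linear regression of log MSD on log lag time, with weights equal
#' to the number of displacement pairs per lag.  The slope is the anomalous
#' diffusion exponent alpha: alpha ~ 1 for Brownian motion, 3/4 for an
#' untensioned thermally fluctuating semiflexible filament, 1/2 for a
#' tension-dominated filament.
#'
#' @param msd an `msd_result` from [compute_msd()].
#' @param fit_range length-2 numeric, lag-time window (s) to fit over.
#'   The default covers the first five lag points (capped at one quarter
#'   of the track duration): long-lag values of a single-trajectory
#'   time-averaged MSD are few-sample and strongly correlated, so the
#'   variance of the fitted exponent grows monotonically as the window is
#'   extended, and is smallest for short-lag fits.  When localization
#'   noise is appreciable, supply a window starting where the MSD clears
#'   the noise floor; for filament regimes use the physics-based window
#'   of [intermediate_lag_window()].
#' @return Object of class `msd_powerlaw`: list with `alpha`,
#'   `alpha_stderr`, `prefactor` (MSD at tau = 1 s), `fit_range`, `n_lags`
#'   and the underlying `lm` fit.
#' @export
fit_msd_exponent <- function(msd, fit_range = NULL) {
  stopifnot(inherits(msd, "msd_result"))
  if (is.null(fit_range)) {
    duration <- attr(msd, "duration")
    if (is.null(duration)) duration <- max(msd$tau) * 2
    hi <- min(msd$tau[min(5L, nrow(msd))], duration / 4)
    # never fewer than 4 lag points
    hi <- max(hi, msd$tau[min(4L, nrow(msd))])
    fit_range <- c(msd$tau[1L], hi)
  }
  sel <- msd$tau >= fit_range[1L] & msd$tau <= fit_range[2L] & msd$msd > 0
  if (sum(sel) < 4L) stop("fewer than 4 usable lags in the fit range")
  d <- data.frame(lt = log(msd$tau[sel]), lm_ = log(msd$msd[sel]),
                  w = msd$n_pairs[sel])
  fit <- lm(lm_ ~ lt, data = d, weights = w)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[["lt"]]
  structure(list(alpha = unname(cf[["lt"]]),
                 alpha_stderr = se,
                 prefactor = exp(unname(cf[["(Intercept)"]])),
                 fit_range = fit_range, n_lags = sum(sel), fit = fit),
            class = "msd_powerlaw")
}

#' @export
print.msd_powerlaw <- function(x, ...) {
  cat(sprintf("MSD power law: alpha = %.4f +/- %.4f (%d lags, tau in [%g, %g] s)\n",
              x$alpha, x$alpha_stderr, x$n_lags, x$fit_range[1L],
              x$fit_range[2L]))
  invisible(x)
}

#' @export
coef.msd_powerlaw <- function(object, ...)
  c(alpha = object$alpha, prefactor = object$prefactor)

#' Summarise a population of MSD exponents
#'
#' Fits a lognormal distribution to the exponents (maximum likelihood on the
#' samples by default; optionally a least-squares fit to a histogram) and
#' classifies each exponent: sub-diffusive (alpha < 1), super-diffusive
#' (1 < alpha < 2), with an additional strongly sub-diffusive cut at
#' `strong_cut` (alpha < 0.4 by default; alpha >= 0.4 counts as thermalised
#' or active).
#'
#' @param alphas numeric vector of fitted exponents (> 0); non-positive
#'   values are excluded with a warning.
#' @param strong_cut threshold for the strongly sub-diffusive flag.
#' @param method "mle" (default) or "histogram".
#' @param breaks histogram breaks for `method = "histogram"`.
#' @return List with `mean` (lognormal distribution mean), `sem` (delta
#'   method standard error of that mean), `meanlog`, `sdlog`, `n`, and
#'   `classification`, a data frame with per-exponent labels and flags.
#' @export
summarize_exponents <- function(alphas, strong_cut = 0.4, method = "mle",
                                breaks = "Sturges") {
  if (any(alphas <= 0, na.rm = TRUE) || any(is.na(alphas))) {
    warning("excluding non-positive or missing exponents")
    alphas <- alphas[!is.na(alphas) & alphas > 0]
  }
  n <- length(alphas)
  if (n < 3L) stop("need at least 3 exponents")
  method <- match.arg(method, c("mle", "histogram"))
  if (method == "mle") {
    ml <- mean(log(alphas))
    s2 <- mean((log(alphas) - ml)^2)   # MLE variance
  } else {
    h <- graphics::hist(alphas, breaks = breaks, plot = FALSE)
    mids <- h$mids[h$density > 0 & h$mids > 0]
    dens <- h$density[h$density > 0 & h$mids > 0]
    obj <- function(p) sum((dens - stats::dlnorm(mids, p[1L],
                                                 exp(p[2L])))^2)
    opt <- optim(c(mean(log(alphas)), log(sd(log(alphas)) + 1e-6)), obj)
    ml <- opt$par[1L]; s2 <- exp(opt$par[2L])^2
  }
  m <- exp(ml + s2 / 2)
  # delta method: var(mean) ~ m^2 (s2/n + s2^2/(2n))
  sem <- m * sqrt(s2 / n + s2^2 / (2 * n))
  cls <- data.frame(
    alpha = alphas,
    regime = ifelse(alphas < 1, "sub-diffusive",
                    ifelse(alphas > 1, "super-diffusive", "diffusive")),
    strongly_subdiffusive = alphas < strong_cut)
  list(mean = m, sem = sem, meanlog = ml, sdlog = sqrt(s2), n = n,
       classification = cls)
}
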