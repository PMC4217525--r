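#' Sample autocorrelation function of a trajectory
#'
#' Mean-removed, biased (1/N-normalized) sample autocorrelation of the
#' free-calcium series, normalized to 1 at lag 0. The biased normalization
#' keeps the estimate positive semi-definite.
#'
#' @param traj A `ca_trajectory` (or a plain numeric vector together with
#'   `dt`).
#' @param max_lag Largest lag (ms).
#' @param species Column to analyze (default `"X"`).
#' @param dt Sampling interval (ms); taken from the trajectory when given.
#' @return An object of class `ca_acf`: a list with `lags` (ms) and
#'   `values` (dimensionless, `values[1] == 1` at lag 0).
#' @examples
#' np <- make_noise_params(0, 0.5, 1)
#' a <- autocorrelation(oup_simulate(np, t_end = 1000, seed = 1,
#'                                   exact = TRUE), max_lag = 2)
#' @export
autocorrelation <- function(traj, max_lag, species = "X", dt = NULL) {
  if (inherits(traj, "ca_trajectory")) {
    x <- traj_series(traj, species)
    dt <- traj$dt
  } else {
    x <- as.numeric(traj)
    if (is.null(dt)) stop("'dt' is required for a plain numeric series")
  }
  if (!is.numeric(max_lag) || max_lag <= 0) stop("'max_lag' must be positive")
  n_lag <- floor(max_lag / dt)
  if (length(x) < 10 * n_lag)
    stop("trajectory too short: need length >= 10 * max_lag / dt")
  if (stats::sd(x) == 0)
    stop("series is constant; autocorrelation is undefined")
  a <- stats::acf(x, lag.max = n_lag, plot = FALSE, demean = TRUE,
                  type = "correlation")
  structure(list(lags = a$lag[, 1, 1] * dt, values = a$acf[, 1, 1], dt = dt),
            class = "ca_acf")
}

#' @export
print.ca_acf <- function(x, ...) {
  cat(sprintf("<ca_acf> %d lags up to %g ms (dt = %g ms)\n",
              length(x$lags) - 1L, x$lags[length(x$lags)], x$dt))
  invisible(x)
}

#' @export
plot.ca_acf <- function(x, ...) {
  graphics::plot(x$lags, x$values, type = "h", xlab = "lag (ms)",
                 ylab = "autocorrelation", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Estimate the autocorrelation time from an ACF
#'
#' Fits an ordinary least-squares line to `log(values)` over the contiguous
#' initial lag range where the autocorrelation exceeds 0.05, and returns
#' `tau_hat = -1 / slope`. For a mono-exponential ACF (the stationary
#' processes produced by this package are mono-exponential by construction)
#' this recovers the decay time; the 0.05 threshold keeps the noisy tail
#' out of the fit.
#'
#' @param acf A `ca_acf` from [autocorrelation()].
#' @param threshold Inclusion threshold on the ACF value (default 0.05).
#' @return Estimated autocorrelation time (ms).
#' @examples
#' a <- structure(list(lags = seq(0, 2, by = 0.01),
#'                     values = exp(-seq(0, 2, by = 0.01) / 0.516),
#'                     dt = 0.01), class = "ca_acf")
#' estimate_tau(a)  # 0.516
#' @export
estimate_tau <- function(acf, threshold = 0.05) {
  stopifnot(inherits(acf, "ca_acf"))
  above <- acf$values > threshold
  n_head <- if (all(above)) length(above) else which(!above)[1L] - 1L
  if (n_head < 3L)
    stop("fewer than 3 usable lags above the threshold; use a smaller dt ",
         "or a longer trajectory")
  idx <- seq_len(n_head)
  fit <- lsfit(acf$lags[idx], log(acf$values[idx]))
  slope <- fit$coefficients[["X"]]
  if (!is.finite(slope) || slope >= 0)
    stop("autocorrelation does not decay over the fit range; ",
         "cannot estimate tau")
  -1 / slope
}

#' Relaxation time constant from a perturbed trajectory
#'
#' For a trajectory started away from equilibrium, fits
#' `log|X_t - x_eq|` against time by ordinary least squares over the
#' initial window where the deviation exceeds 10% of its initial value,
#' and returns `tau_hat = -1 / slope`. Interior points where the deviation
#' is zero or has crossed the equilibrium are dropped from the fit. Under
#' the excess buffer approximation the decay is mono-exponential with rate
#' `K1`, so `tau_hat` estimates `1 / K1` — the same time constant as the
#' stationary noise autocorrelation time.
#'
#' @param traj A `ca_trajectory` with initial value away from `x_eq`.
#' @param x_eq Equilibrium (asymptotic) free-calcium count the trajectory
#'   relaxes to.
#' @param window_frac Fit window: points with deviation above this fraction
#'   of the initial deviation (default 0.1).
#' @return Estimated relaxation time constant (ms).
#' @export
fit_relaxation <- function(traj, x_eq, window_frac = 0.1) {
  stopifnot(inherits(traj, "ca_trajectory"))
  x <- traj_series(traj)
  d0 <- x[1L] - x_eq
  if (d0 == 0) stop("trajectory starts at x_eq; no relaxation to fit")
  d <- sign(d0) * (x - x_eq)
  n_head <- which(d <= window_frac * abs(d0))[1L]
  if (is.na(n_head)) n_head <- length(d) + 1L
  idx <- seq_len(n_head - 1L)
  idx <- idx[d[idx] > 0]
  if (length(idx) < 5L)
    stop("fewer than 5 usable points in the relaxation window; ",
         "use a smaller dt or a larger initial perturbation")
  fit <- lsfit(traj$time[idx], log(d[idx]))
  slope <- fit$coefficients[["X"]]
  if (!is.finite(slope) || slope >= 0)
    stop("deviation does not decay over the fit window")
  -1 / slope
}

#' Summary statistics of a trajectory
#'
#' Sample mean, sample standard deviation (denominator N-1) and estimated
#' autocorrelation time (via [autocorrelation()] and [estimate_tau()]) of
#' the free-calcium series.
#'
#' @param traj A `ca_trajectory` of length >= 100.
#' @param max_lag Largest ACF lag (ms) for the tau estimate; defaults to
#'   one tenth of the trajectory span, capped at 1000 sampling steps.
#' @return An object of class `ca_summary` with fields `mean`, `sd`,
#'   `tau_hat` (`NA` with a flag if the series is constant) and
#'   `n_samples`.
#' @export
summary_stats <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "ca_trajectory"))
  x <- traj_series(traj)
  if (length(x) < 100L) stop("trajectory too short (need >= 100 samples)")
  m <- mean(x)
  s <- stats::sd(x)
  if (is.null(max_lag)) {
    span <- traj$time[length(traj$time)] - traj$t0
    max_lag <- min(span / 10, 1000 * traj$dt)
  }
  tau_hat <- if (s == 0) NA_real_ else
    tryCatch(estimate_tau(autocorrelation(traj, max_lag = max_lag)),
             error = function(e) NA_real_)
  structure(list(mean = m, sd = s, tau_hat = tau_hat,
                 n_samples = length(x), degenerate = s == 0),
            class = "ca_summary")
}

#' @export
print.ca_summary <- function(x, ...) {
  cat(sprintf(
    "<ca_summary> mean = %.4g, sd = %.4g, tau_hat = %s ms (n = %d)\n",
    x$mean, x$sd,
    if (is.na(x$tau_hat)) "NA" else sprintf("%.4g", x$tau_hat),
    x$n_samples))
  invisible(x)
}
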