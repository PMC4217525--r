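#' Specify a double-well system
#'
#' The potential is `V(x) = -a/2 x^2 + b/4 x^4`, a symmetric double well
#' with minima at `x = +/- sqrt(a/b)` and barrier height `a^2 / (4 b)` at
#' the origin. With `a = b = 1` (the canonical normalization of the
#' colored-noise literature) the wells sit at +/-1 and the barrier is 0.25.
#' The two wells stand in for the two functional states of a
#' calcium-sensitive bistable element, e.g. an ion channel's open and
#' closed states.
#'
#' @param a Quadratic coefficient, > 0.
#' @param b Quartic coefficient, > 0.
#' @param dt Integration step (ms), > 0.
#' @param x0 Initial state; defaults to the right-hand minimum.
#' @return An object of class `double_well`.
#' @export
double_well <- function(a = 1, b = 1, dt = 0.01, x0 = sqrt(a / b)) {
  if (!is.numeric(a) || a <= 0) stop("'a' must be positive")
  if (!is.numeric(b) || b <= 0) stop("'b' must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(a = a, b = b, dt = dt, x0 = x0), class = "double_well")
}

#' @export
print.double_well <- function(x, ...) {
  cat(sprintf(
    "<double_well> V(x) = -%g/2 x^2 + %g/4 x^4; minima at +/-%g, barrier %g\n",
    x$a, x$b, sqrt(x$a / x$b), x$a^2 / (4 * x$b)))
  invisible(x)
}

#' Force field of the double-well potential
#'
#' Returns the negative potential gradient `-dV/dx = a x - b x^3`. Zero at
#' the origin (unstable fixed point) and at the two minima.
#'
#' @param x State value(s).
#' @param spec A [double_well()].
#' @return Force, same length as `x`.
#' @examples
#' dw_gradient(2, double_well(a = 1, b = 1))  # -6
#' @export
dw_gradient <- function(x, spec) {
  stopifnot(inherits(spec, "double_well"))
  if (any(!is.finite(x))) stop("'x' must be finite")
  spec$a * x - spec$b * x^3
}

#' Integrate double-well motion driven by a noise trajectory
#'
#' First-order Euler scheme
#' `X[k+1] = X[k] + (a X[k] - b X[k]^3) dt + xi[k]`, where the supplied
#' noise samples enter as per-step additive increments. The noise mean is
#' removed before integration to respect the symmetry of the potential
#' about the origin (scaling a white-noise sequence by `sqrt(dt)` recovers
#' the standard white-noise limit).
#'
#' @param noise A `ca_trajectory` (e.g. from [oup_simulate()]) whose `dt`
#'   must equal `spec$dt`, or a plain numeric vector of increments.
#' @param spec A [double_well()].
#' @return A `ca_trajectory` of the state variable, aligned with the noise
#'   grid.
#' @examples
#' dw <- double_well()
#' xi <- oup_simulate(make_noise_params(0, 0.75, 1), dt = 0.01,
#'                    t_end = 100, seed = 1, exact = TRUE)
#' x <- dw_simulate(xi, dw)
#' @export
dw_simulate <- function(noise, spec) {
  stopifnot(inherits(spec, "double_well"))
  if (inherits(noise, "ca_trajectory")) {
    if (!isTRUE(all.equal(noise$dt, spec$dt)))
      stop("noise trajectory dt (", noise$dt, ") does not match spec dt (",
           spec$dt, ")")
    xi <- traj_series(noise)
  } else {
    xi <- as.numeric(noise)
  }
  xi <- xi - mean(xi)  # enforce zero-mean driving
  # xi[k] drives the step from X[k] to X[k+1]; the last sample is unused so
  # state and noise grids stay aligned.
  inc <- xi[-length(xi)]
  X <- dw_path_cpp(spec$x0, spec$a, spec$b, spec$dt, inc)
  new_trajectory(seq(0, by = spec$dt, length.out = length(X)), X, spec$dt,
                 engine = "double-well",
                 meta = list(a = spec$a, b = spec$b))
}

#' Empirical joint distribution of noise and state
#'
#' Normalized 2-D histogram of paired samples `(xi_t, X_t)` on equal-width
#' bins spanning the range of each series. The density integrates to 1
#' (sums to 1 after multiplying by the bin areas).
#'
#' @param xi,x `ca_trajectory` objects or numeric vectors of equal length.
#' @param n_bins Number of bins per axis, >= 10.
#' @return An object of class `joint_distribution` with `xi_edges`,
#'   `x_edges` (bin boundaries) and `density` (matrix, xi in rows).
#' @export
joint_distribution <- function(xi, x, n_bins = 50) {
  if (inherits(xi, "ca_trajectory")) xi <- traj_series(xi)
  if (inherits(x, "ca_trajectory")) x <- traj_series(x)
  if (length(xi) != length(x)) stop("'xi' and 'x' must have equal length")
  if (!is.numeric(n_bins) || n_bins < 10) stop("'n_bins' must be >= 10")
  n_bins <- as.integer(n_bins)
  xi_edges <- seq(min(xi), max(xi), length.out = n_bins + 1L)
  x_edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  i <- findInterval(xi, xi_edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  j <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, n_bins, n_bins)
  tab <- table(factor(i, levels = seq_len(n_bins)),
               factor(j, levels = seq_len(n_bins)))
  counts[] <- as.numeric(tab)
  area <- diff(xi_edges)[1L] * diff(x_edges)[1L]
  structure(list(xi_edges = xi_edges, x_edges = x_edges,
                 density = counts / (length(xi) * area)),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("<joint_distribution> %d x %d bins, xi in [%g, %g], x in [%g, %g]\n",
              nrow(x$density), ncol(x$density),
              x$xi_edges[1L], x$xi_edges[length(x$xi_edges)],
              x$x_edges[1L], x$x_edges[length(x$x_edges)]))
  invisible(x)
}

#' @export
plot.joint_distribution <- function(x, ...) {
  graphics::image(
    x = (x$xi_edges[-1L] + x$xi_edges[-length(x$xi_edges)]) / 2,
    y = (x$x_edges[-1L] + x$x_edges[-length(x$x_edges)]) / 2,
    z = x$density, xlab = "noise xi", ylab = "state X", ...)
  invisible(x)
}

#' L1 distance between a joint density and the product of its marginals
#'
#' A factorization diagnostic: 0 means the two variables are independent
#' at the histogram resolution.
#'
#' @param jd A [joint_distribution()].
#' @return `sum |P(xi, x) - P(xi) P(x)|` times the bin area, in `[0, 2]`.
#' @export
factorization_distance <- function(jd) {
  stopifnot(inherits(jd, "joint_distribution"))
  d_xi <- diff(jd$xi_edges)[1L]
  d_x <- diff(jd$x_edges)[1L]
  p <- jd$density * d_xi * d_x         # cell probabilities
  prod <- outer(rowSums(p), colSums(p))
  sum(abs(p - prod))
}

#' Correlation between driving noise and driven state
#'
#' Pearson correlation coefficient between paired samples of the noise
#' variable and the double-well state variable. For slow (strongly
#' colored) noise the state tracks the noise sign, producing a strong
#' positive correlation; for fast noise the correlation vanishes.
#'
#' @param xi,x `ca_trajectory` objects or numeric vectors of equal length
#'   (>= 1e4 samples).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
coupling_correlation <- function(xi, x) {
  if (inherits(xi, "ca_trajectory")) xi <- traj_series(xi)
  if (inherits(x, "ca_trajectory")) x <- traj_series(x)
  if (length(xi) != length(x)) stop("'xi' and 'x' must have equal length")
  if (length(xi) < 1e4)
    stop("need at least 1e4 paired samples for a stable estimate")
  if (stats::sd(xi) == 0 || stats::sd(x) == 0)
    stop("zero variance in one of the series")
  stats::cor(xi, x)
}
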