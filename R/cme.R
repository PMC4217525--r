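#' Stationary distribution of the chemical master equation
#'
#' For a closed single-buffer system the conservation laws reduce the state
#' to the free-calcium count `X` alone: `Z = X_T - X` and
#' `Y = Y_T - Z`, with integer totals `X_T` (free plus bound calcium) and
#' `Y_T` (free plus bound buffer) fixed by the rounded initial state. The
#' master equation is then a finite birth-death chain on
#' `X in [max(0, X_T - Y_T), X_T]` with up-rate `c_minus * (X_T - X)` and
#' down-rate `c_plus * X * (Y_T - X_T + X)`. The stationary distribution is
#' obtained as the null space of the (tridiagonal) generator, normalized to
#' sum to one. This provides an exact oracle against which SSA occupancy
#' statistics can be validated.
#'
#' @param system A single-buffer [ca_system()] without diffusion, small
#'   enough that `X_T <= 200` and total buffer `<= 2000` counts.
#' @return A named numeric vector of stationary probabilities indexed by
#'   the value of `X`.
#' @examples
#' sys <- ca_system("CaM", volume = 0.005, ca_eq = 0.1)
#' p <- cme_stationary(sys)
#' sum(p)  # 1
#' @export
cme_stationary <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  if (n_buffers(system) != 1L)
    stop("cme_stationary() requires a single-buffer system")
  if (!is.null(system$D_Ca))
    stop("cme_stationary() requires a closed system (no diffusion)")
  eq <- equilibrium_state(system)
  rates <- stochastic_rates(system)
  X0 <- round(eq$counts$x_eq)
  Z0 <- round(eq$counts$z_eq[[1L]])
  Y0 <- round(eq$counts$y_eq[[1L]])
  X_T <- X0 + Z0
  Y_T <- Y0 + Z0
  if (X_T > 200) stop("state space too large: X_T = ", X_T, " counts > 200")
  if (Y_T > 2000) stop("state space too large: total buffer = ", Y_T,
                       " counts > 2000")

  states <- seq.int(max(0, X_T - Y_T), X_T)
  n <- length(states)
  up <- rates$c_minus[[1L]] * (X_T - states)            # X -> X + 1
  down <- rates$c_plus[[1L]] * states * (Y_T - X_T + states)  # X -> X - 1

  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) Q[i, i + 1L] <- up[i]
    if (i > 1L) Q[i, i - 1L] <- down[i]
    Q[i, i] <- -(up[i] * (i < n) + down[i] * (i > 1L))
  }
  # solve pi Q = 0 with sum(pi) = 1: replace one balance equation
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- solve(A, b)
  p[p < 0 & p > -1e-12] <- 0  # numerical dust
  p <- p / sum(p)
  names(p) <- states
  p
}

#' Mean and variance of a discrete distribution over counts
#'
#' Helper for distributions returned by [cme_stationary()] and
#' [state_occupancy()].
#'
#' @param p Named probability vector (names are integer states).
#' @return A list with `mean` and `var`.
#' @export
distribution_moments <- function(p) {
  x <- as.numeric(names(p))
  m <- sum(x * p)
  list(mean = m, var = sum((x - m)^2 * p))
}

#' Total-variation distance between two count distributions
#'
#' Aligns the supports by state label and returns
#' `0.5 * sum(|p - q|)`.
#'
#' @param p,q Named probability vectors indexed by integer state.
#' @return Total-variation distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  states <- sort(unique(c(as.numeric(names(p)), as.numeric(names(q)))))
  pv <- p[as.character(states)]
  qv <- q[as.character(states)]
  pv[is.na(pv)] <- 0
  qv[is.na(qv)] <- 0
  0.5 * sum(abs(pv - qv))
}
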