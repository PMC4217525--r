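#' Linearized single-buffer kinetics under the excess buffer approximation
#'
#' With the free buffer pinned at its equilibrium value (excess buffer
#' approximation, EBA), the free-calcium concentration obeys the linear ODE
#' `dx/dt = -K1 x + K2` with `K1 = k_plus * y_eq + k_minus` (ms^-1) and
#' `K2 = k_minus * x_T` (uM ms^-1), so that `x_eq = K2 / K1`. The stochastic
#' analogues in count units are `C1 = c_plus * Y_eq + c_minus` (numerically
#' equal to `K1`, since the volume cancels) and `C2 = c_minus * X_T`.
#'
#' @param system A single-buffer [ca_system()].
#' @return A list of class `linear_kinetics` with `K1`, `K2`, `C1`, `C2`.
#' @examples
#' linear_kinetics(ca_system("CaM", ca_eq = 0.1))$K1  # 1.938 ms^-1
#' @export
linear_kinetics <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  if (n_buffers(system) != 1L)
    stop("linear_kinetics() requires a single-buffer system")
  eq <- equilibrium_state(system)
  b <- system$buffers[[1L]]
  rates <- stochastic_rates(system)
  K1 <- b$k_plus * eq$y_eq[[1L]] + b$k_minus
  K2 <- b$k_minus * eq$x_T
  C1 <- rates$c_plus[[1L]] * eq$counts$y_eq[[1L]] + rates$c_minus[[1L]]
  C2 <- rates$c_minus[[1L]] * eq$counts$x_T
  structure(list(K1 = K1, K2 = K2, C1 = C1, C2 = C2),
            class = "linear_kinetics")
}

#' Deterministic mono-exponential relaxation
#'
#' Under the excess buffer approximation the free-calcium concentration
#' relaxes mono-exponentially to equilibrium:
#' `x(t) = (x0 - x_eq) * exp(-K1 t) + x_eq`.
#'
#' @param x0 Initial free-calcium concentration (uM).
#' @param system A single-buffer [ca_system()].
#' @param times Evaluation times (ms), >= 0.
#' @return Numeric vector of concentrations at `times`.
#' @export
deterministic_relaxation <- function(x0, system, times) {
  if (any(times < 0)) stop("'times' must be non-negative")
  K1 <- linear_kinetics(system)$K1
  (x0 - system$ca_eq) * exp(-K1 * times) + system$ca_eq
}

#' Theoretical noise autocorrelation time
#'
#' Stationary autocorrelation time of the free-calcium fluctuations in the
#' Ornstein-Uhlenbeck surrogate obtained from the excess-buffer-approximated
#' chemical Langevin equation:
#' `tau = 1 / (sum_j (k_plus_j * y_eq_j + k_minus_j) + c_d)`,
#' with free-buffer concentrations `y_eq_j` in uM and `c_d = D_Ca / L^2`
#' (0 when diffusion is off). The relaxation rates of all buffer channels
#' and of diffusion add in the linearized drift, so faster or more abundant
#' buffers, and diffusive exchange, shorten the correlation time. The value
#' is independent of the reaction volume.
#'
#' @param system A [ca_system()] with at least one buffer or diffusion.
#' @return Autocorrelation time in ms.
#' @examples
#' tau_theory(ca_system("CaM", ca_eq = 0.1))            # 0.516 ms
#' tau_theory(ca_system(c("CaM", "EGTA"), ca_eq = 0.1)) # 0.483 ms
#' @export
tau_theory <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  eq <- equilibrium_state(system)
  rates <- stochastic_rates(system)
  denom <- rates$c_d
  if (n_buffers(system) > 0L)
    denom <- denom + sum(buffer_field(system, "k_plus") * eq$y_eq +
                           buffer_field(system, "k_minus"))
  if (denom <= 0)
    stop("system has no relaxation channel (no buffers, no diffusion)")
  1 / denom
}

#' Theoretical noise volatility
#'
#' Stationary volatility (diffusion amplitude) of the Ornstein-Uhlenbeck
#' surrogate, in copy-number units:
#' `sigma = sqrt(sum_j (c_plus_j X_eq Y_eq_j + c_minus_j Z_eq_j) + 2 c_d X_eq)`
#' where counts are equilibrium copy numbers in the system volume. At
#' equilibrium, detailed balance makes each buffer's two terms equal, and
#' the influx/efflux diffusion channels each contribute `c_d X_eq`.
#'
#' @param system A [ca_system()].
#' @return Volatility in counts * ms^(-1/2); scales as `sqrt(volume)`.
#' @examples
#' sigma_theory(ca_system("CaM", volume = 0.125, ca_eq = 0.1))  # ~5.35
#' @export
sigma_theory <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  eq <- equilibrium_state(system)
  rates <- stochastic_rates(system)
  s2 <- 2 * rates$c_d * eq$counts$x_eq
  if (n_buffers(system) > 0L)
    s2 <- s2 + sum(rates$c_plus * eq$counts$x_eq * eq$counts$y_eq +
                     rates$c_minus * eq$counts$z_eq)
  sqrt(s2)
}

#' Theoretical stationary mean
#'
#' Stationary mean of the Ornstein-Uhlenbeck surrogate in copy numbers:
#' `mu = sum_j c_minus_j (X_T - sum_{i != j} Z_eq_i) /
#'       sum_j (c_plus_j Y_eq_j + c_minus_j)`
#' for the multi-buffer system (and its single-buffer special case
#' `C2 / C1`). Algebraically this always equals the equilibrium free-calcium
#' copy number `X_eq`; the explicit form is evaluated here and serves as a
#' consistency check of the reduction.
#'
#' @param system A [ca_system()] with at least one buffer; with no buffers
#'   the equilibrium count itself is returned.
#' @return Stationary mean in counts.
#' @export
mu_theory <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  eq <- equilibrium_state(system)
  M <- n_buffers(system)
  if (M == 0L) return(eq$counts$x_eq)
  rates <- stochastic_rates(system)
  Z <- eq$counts$z_eq
  XT <- eq$counts$x_T
  num <- sum(vapply(seq_len(M), function(j)
    rates$c_minus[j] * (XT - sum(Z[-j])), numeric(1)))
  den <- sum(rates$c_plus * eq$counts$y_eq + rates$c_minus)
  num / den
}

#' Stationary variance of an Ornstein-Uhlenbeck process
#'
#' @param sigma Volatility (counts * ms^(-1/2)), >= 0.
#' @param tau Autocorrelation time (ms), > 0.
#' @return `sigma^2 * tau / 2` (counts^2).
#' @export
ou_variance <- function(sigma, tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("'tau' must be positive")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be non-negative")
  sigma^2 * tau / 2
}

#' Ornstein-Uhlenbeck surrogate parameters of a microdomain
#'
#' Bundles the three stationary noise parameters of the free-calcium
#' fluctuations — mean `mu` (counts), autocorrelation time `tau` (ms) and
#' volatility `sigma` (counts * ms^(-1/2)) — together with the implied
#' stationary variance `sigma^2 * tau / 2`.
#'
#' @param system A [ca_system()].
#' @return An object of class `noise_params` with fields `mu`, `tau`,
#'   `sigma`, `variance`, and `volume` (fl, for unit conversions).
#' @examples
#' noise_params(ca_system("CaM", volume = 0.125, ca_eq = 0.1))
#' @export
noise_params <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  tau <- tau_theory(system)
  sigma <- sigma_theory(system)
  structure(
    list(mu = mu_theory(system), tau = tau, sigma = sigma,
         variance = ou_variance(sigma, tau), volume = system$volume),
    class = "noise_params")
}

#' Construct noise parameters directly
#'
#' For driving downstream models with a hand-specified colored-noise
#' process, independent of any chemical system.
#'
#' @param mu Stationary mean (counts).
#' @param tau Autocorrelation time (ms), > 0.
#' @param sigma Volatility (counts * ms^(-1/2)), >= 0.
#' @return A `noise_params` object.
#' @export
make_noise_params <- function(mu, tau, sigma) {
  structure(
    list(mu = mu, tau = tau, sigma = sigma,
         variance = ou_variance(sigma, tau), volume = NA_real_),
    class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "<noise_params> mu = %.4g counts, tau = %.4g ms, sigma = %.4g counts/sqrt(ms)\n  stationary variance = %.4g counts^2 (sd = %.4g)\n",
    x$mu, x$tau, x$sigma, x$variance, sqrt(x$variance)))
  invisible(x)
}
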