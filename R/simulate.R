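#' Exact stochastic simulation (Gillespie direct method)
#'
#' Generates an exact sample path of the chemical master equation for a
#' buffered calcium microdomain using the direct method: exponential
#' waiting times at the total propensity, one reaction selected per event
#' in proportion to its propensity. Reactions are per-buffer binding
#' (propensity `c_plus * X * Y_j`) and unbinding (`c_minus * Z_j`), plus,
#' when diffusion is enabled, efflux (`c_d * X`) and constant-pool influx
#' (constant rate `c_d * X_eq`, with the real-valued equilibrium count).
#'
#' Initial copy numbers are the equilibrium values rounded half-to-even,
#' except that the free-calcium start value can be overridden with `x0`
#' (buffers always start at their `ca_eq` equilibrium).
#'
#' @param system A [ca_system()].
#' @param t_end End time (ms), > 0.
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @param x0 Optional initial free-calcium concentration (uM); defaults to
#'   the system's `ca_eq`.
#' @param max_events Safety cap on the number of simulated events.
#' @return An object of class `jump_path`: a list with `times` (event times
#'   in ms, starting at 0), `states` (integer-valued matrix with columns
#'   `X`, then `Y.<name>`, `Z.<name>` per buffer), and `meta`. If the total
#'   propensity reaches zero the path terminates early at the absorbing
#'   state with a warning.
#' @examples
#' sys <- ca_system("CaM", volume = 0.125, ca_eq = 0.1)
#' path <- ssa_simulate(sys, t_end = 10, seed = 1)
#' @export
ssa_simulate <- function(system, t_end, seed = NULL, x0 = NULL,
                         max_events = 2e7) {
  stopifnot(inherits(system, "ca_system"))
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (!is.null(x0) && (!is.numeric(x0) || x0 < 0))
    stop("'x0' must be non-negative (uM)")
  eq <- equilibrium_state(system)
  rates <- stochastic_rates(system)
  M <- n_buffers(system)

  X0 <- round(concentration_to_count(if (is.null(x0)) system$ca_eq else x0,
                                     system$volume))
  Z0 <- round(eq$counts$z_eq)
  Y0 <- round(eq$counts$y_eq)
  yT <- Y0 + Z0  # conserved per-buffer totals, integer

  influx <- rates$c_d * eq$counts$x_eq  # real-valued equilibrium count
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_path_cpp(X0, as.numeric(yT), as.numeric(Z0),
                      as.numeric(rates$c_plus), as.numeric(rates$c_minus),
                      rates$c_d, influx, t_end, max_events)
  if (res$absorbed)
    warning("total propensity reached zero; path terminated at the ",
            "absorbing state before t_end")
  if (res$truncated)
    warning("event cap 'max_events' reached before t_end")

  nms <- vapply(system$buffers, `[[`, "", "name")
  states <- cbind(X = res$X,
                  matrix(rep(yT, each = length(res$X)) - res$Z, ncol = M,
                         dimnames = list(NULL, if (M) paste0("Y.", nms))),
                  matrix(res$Z, ncol = M,
                         dimnames = list(NULL, if (M) paste0("Z.", nms))))
  structure(
    list(times = res$times, states = states,
         meta = list(engine = "ssa", seed = seed,
                     system = system_digest(system),
                     t_end = t_end, n_events = res$n_events,
                     absorbed = res$absorbed, truncated = res$truncated)),
    class = "jump_path")
}

#' @export
print.jump_path <- function(x, ...) {
  cat(sprintf("<jump_path> %g events over [0, %g] ms\n",
              x$meta$n_events, x$times[length(x$times)]))
  cat(sprintf("  species: %s\n", paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Resample a jump path onto a uniform grid
#'
#' Interpolates the piecewise-constant jump path at equidistant times.
#' Linear interpolation between surrounding event states is the default
#' (the convention used before statistical processing); `method = "hold"`
#' uses the measure-theoretically exact zero-order hold, appropriate when
#' comparing occupancy statistics with the chemical master equation.
#'
#' @param path A `jump_path` from [ssa_simulate()].
#' @param dt Sampling interval (ms), > 0.
#' @param method `"linear"` (default) or `"hold"`.
#' @return A `ca_trajectory` on the grid `seq(0, t_last, by = dt)` with
#'   `floor(t_last / dt) + 1` samples.
#' @export
resample_path <- function(path, dt = 0.01, method = c("linear", "hold")) {
  stopifnot(inherits(path, "jump_path"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  method <- match.arg(method)
  t_last <- path$times[length(path$times)]
  grid <- seq(0, t_last, by = dt)
  vals <- apply(path$states, 2L, function(y) {
    if (length(path$times) == 1L) return(rep(y, length(grid)))
    approx(path$times, y, xout = grid,
           method = if (method == "linear") "linear" else "constant",
           f = 0, rule = 2)$y
  })
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = length(grid),
                   dimnames = list(NULL, colnames(path$states)))
  new_trajectory(grid, vals, dt, engine = path$meta$engine,
                 seed = path$meta$seed,
                 meta = c(list(interpolation = method),
                          path$meta[setdiff(names(path$meta),
                                            c("engine", "seed"))]))
}

#' Time-weighted occupancy distribution of the free-calcium count
#'
#' Computes the empirical stationary distribution of `X` from a jump path
#' by weighting each visited state with its holding time (the exact
#' path-measure estimate, unaffected by interpolation).
#'
#' @param path A `jump_path`.
#' @param t_burn Initial time span (ms) discarded as burn-in.
#' @return A named numeric vector: probabilities indexed by the integer
#'   value of `X`.
#' @export
state_occupancy <- function(path, t_burn = 0) {
  stopifnot(inherits(path, "jump_path"))
  times <- c(path$times, path$meta$t_end)
  hold <- diff(times)
  keep <- times[-length(times)] >= t_burn & hold > 0
  x <- path$states[keep, "X"]
  w <- hold[keep]
  p <- tapply(w, factor(x, levels = sort(unique(x))), sum)
  p <- p / sum(p)
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

# shared setup for the two CLE variants
cle_setup <- function(system, x0) {
  eq <- equilibrium_state(system)
  rates <- stochastic_rates(system)
  list(
    eq = eq, rates = rates,
    X0 = concentration_to_count(if (is.null(x0)) system$ca_eq else x0,
                                system$volume),
    Z0 = as.numeric(eq$counts$z_eq),
    yT = as.numeric(eq$counts$y_eq + eq$counts$z_eq),
    yeq = as.numeric(eq$counts$y_eq))
}

cle_run <- function(system, dt, t_end, seed, x0, noise, eba, engine) {
  stopifnot(inherits(system, "ca_system"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive")
  s <- cle_setup(system, x0)
  n_steps <- floor(t_end / dt)
  if (!is.null(seed)) set.seed(seed)
  res <- cle_path_cpp(s$X0, s$Z0, s$yT, s$yeq, eba,
                      as.numeric(s$rates$c_plus),
                      as.numeric(s$rates$c_minus),
                      s$rates$c_d, s$eq$counts$x_eq,
                      dt, n_steps, if (noise) 1 else 0)
  if (any(!is.finite(res$X)))
    stop("CLE trajectory contains non-finite values")
  M <- n_buffers(system)
  nms <- vapply(system$buffers, `[[`, "", "name")
  vals <- cbind(X = res$X,
                matrix(res$Z, ncol = M,
                       dimnames = list(NULL, if (M) paste0("Z.", nms))))
  new_trajectory(seq(0, by = dt, length.out = n_steps + 1L), vals, dt,
                 engine = engine, seed = seed,
                 meta = list(system = system_digest(system),
                             n_clamp_propensity = res$n_clamp_propensity,
                             n_clamp_species = res$n_clamp_species))
}

#' Chemical Langevin equation trajectory
#'
#' Euler-Maruyama integration of the chemical Langevin equation for the
#' full system: drift from mass-action rates, one combined Gaussian
#' increment per buffer channel with variance `dt` times the summed
#' binding/unbinding propensities (applied anti-symmetrically to `X` and
#' `Z_j`, conserving per-buffer mass pathwise), and a combined increment
#' for the diffusion channels when enabled. Propensity arguments are
#' clamped at 0 inside square roots and species at 0 after each step;
#' occurrence counts are recorded in the trajectory metadata.
#'
#' @param system A [ca_system()].
#' @param dt Integration step (ms), > 0; default 0.01.
#' @param t_end End time (ms), > 0.
#' @param seed Integer seed, or `NULL`.
#' @param x0 Optional initial free-calcium concentration (uM).
#' @param noise Set `FALSE` to suppress the stochastic terms, leaving the
#'   deterministic mass-action ODE integrated by the Euler method.
#' @return A `ca_trajectory` with columns `X` and `Z.<name>` (counts,
#'   real-valued).
#' @export
cle_simulate <- function(system, dt = 0.01, t_end, seed = NULL, x0 = NULL,
                         noise = TRUE)
  cle_run(system, dt, t_end, seed, x0, noise, eba = FALSE, engine = "cle")

#' Excess-buffer-approximation Langevin trajectory
#'
#' As [cle_simulate()], but with each free-buffer concentration pinned at
#' its equilibrium value (the excess buffer approximation). For a single
#' buffer this reduces the dynamics to a scalar mean-reverting equation
#' for `X` with time-dependent volatility; with the volatility frozen at
#' equilibrium it is exactly an Ornstein-Uhlenbeck generator.
#'
#' @inheritParams cle_simulate
#' @return A `ca_trajectory`.
#' @export
cle_eba_simulate <- function(system, dt = 0.01, t_end, seed = NULL,
                             x0 = NULL, noise = TRUE)
  cle_run(system, dt, t_end, seed, x0, noise, eba = TRUE,
          engine = "cle-eba")

#' Ornstein-Uhlenbeck surrogate trajectory
#'
#' Simulates `dX = -(X - mu)/tau dt + sigma dW`. The default scheme is
#' Euler-Maruyama at step `dt`; with `exact = TRUE` the exact conditional
#' update `X <- mu + (X - mu) e^(-dt/tau) + s N(0,1)` with
#' `s^2 = sigma^2 tau (1 - e^(-2 dt/tau)) / 2` is used, which samples the
#' process without discretization error at any step size.
#'
#' @param params A `noise_params` object ([noise_params()] or
#'   [make_noise_params()]).
#' @param x0 Initial value (counts); defaults to `params$mu`.
#' @param dt Sampling step (ms), > 0.
#' @param t_end End time (ms), > 0.
#' @param seed Integer seed, or `NULL`.
#' @param exact Use the exact discretization instead of Euler-Maruyama.
#' @return A `ca_trajectory` with a single column `X`.
#' @examples
#' np <- make_noise_params(mu = 7.5, tau = 0.516, sigma = 5.35)
#' traj <- oup_simulate(np, t_end = 100, seed = 1, exact = TRUE)
#' @export
oup_simulate <- function(params, x0 = params$mu, dt = 0.01, t_end,
                         seed = NULL, exact = FALSE) {
  stopifnot(inherits(params, "noise_params"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (!is.numeric(params$tau) || params$tau <= 0)
    stop("'tau' must be positive")
  n_steps <- floor(t_end / dt)
  if (!is.null(seed)) set.seed(seed)
  if (exact) {
    alpha <- exp(-dt / params$tau)
    s <- params$sigma * sqrt(params$tau * (1 - alpha^2) / 2)
  } else {
    alpha <- 1 - dt / params$tau
    s <- params$sigma * sqrt(dt)
  }
  innov <- s * rnorm(n_steps)
  dev <- as.numeric(stats::filter(innov, alpha, method = "recursive",
                                  init = x0 - params$mu))
  X <- c(x0, params$mu + dev)
  new_trajectory(seq(0, by = dt, length.out = n_steps + 1L), X, dt,
                 engine = if (exact) "oup-exact" else "oup",
                 seed = seed,
                 meta = list(mu = params$mu, tau = params$tau,
                             sigma = params$sigma))
}

#' Simulate a calcium microdomain with a chosen engine
#'
#' Convenience front-end dispatching to [ssa_simulate()] (resampled at
#' `dt`), [cle_simulate()], [cle_eba_simulate()] or [oup_simulate()] (with
#' parameters from [noise_params()]).
#'
#' @param object A [ca_system()].
#' @param nsim Number of trajectories.
#' @param seed Integer seed for the first trajectory; trajectory `i` uses
#'   `seed + i - 1`.
#' @param engine One of `"ssa"`, `"cle"`, `"cle-eba"`, `"oup"`.
#' @param t_end End time (ms).
#' @param dt Sampling/integration step (ms).
#' @param x0 Optional initial free-calcium concentration (uM).
#' @param ... Passed to the engine.
#' @return A `ca_trajectory` if `nsim = 1`, else a list of them.
#' @export
simulate.ca_system <- function(object, nsim = 1, seed = NULL,
                               engine = c("ssa", "cle", "cle-eba", "oup"),
                               t_end = 100, dt = 0.01, x0 = NULL, ...) {
  engine <- match.arg(engine)
  seeds <- if (is.null(seed)) vector("list", nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  one <- function(s) {
    switch(engine,
      "ssa" = resample_path(ssa_simulate(object, t_end = t_end, seed = s,
                                         x0 = x0, ...), dt = dt),
      "cle" = cle_simulate(object, dt = dt, t_end = t_end, seed = s,
                           x0 = x0, ...),
      "cle-eba" = cle_eba_simulate(object, dt = dt, t_end = t_end, seed = s,
                                   x0 = x0, ...),
      "oup" = {
        np <- noise_params(object)
        x0c <- if (is.null(x0)) np$mu
               else concentration_to_count(x0, object$volume)
        oup_simulate(np, x0 = x0c, dt = dt, t_end = t_end, seed = s, ...)
      })
  }
  out <- lapply(seeds, one)
  if (nsim == 1L) out[[1L]] else out
}
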