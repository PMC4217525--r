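# Shared fixtures: all built in code, no stored data.

cam_system <- function(volume = 0.125, ca_eq = 0.1, D_Ca = NULL)
  ca_system("CaM", volume = volume, ca_eq = ca_eq, D_Ca = D_Ca)

# a small random (but valid) buffered system, reproducible by seed
random_system <- function(seed, M = 2, volume = NULL, D_Ca = NULL) {
  set.seed(seed)
  bufs <- lapply(seq_len(M), function(j)
    buffer_spec(paste0("b", j),
                B_T = 10^runif(1, 0, 3),
                k_plus = 10^runif(1, -3, 0),
                k_minus = 10^runif(1, -3, 1)))
  ca_system(bufs, volume = if (is.null(volume)) 10^runif(1, -2, 1) else volume,
            ca_eq = 10^runif(1, -2, 1), D_Ca = D_Ca)
}

# detailed-balance (product-form) stationary law of the single-buffer
# birth-death chain; independent oracle for cme_stationary()
birth_death_stationary <- function(system) {
  eq <- equilibrium_state(system)
  r <- stochastic_rates(system)
  X_T <- round(eq$counts$x_eq) + round(eq$counts$z_eq[[1L]])
  Y_T <- round(eq$counts$y_eq[[1L]]) + round(eq$counts$z_eq[[1L]])
  states <- seq.int(max(0, X_T - Y_T), X_T)
  logw <- numeric(length(states))
  for (i in seq_along(states)[-1L]) {
    x <- states[i]
    up <- r$c_minus[[1L]] * (X_T - (x - 1))          # (x-1) -> x
    down <- r$c_plus[[1L]] * x * (Y_T - X_T + x)     # x -> (x-1)
    logw[i] <- logw[i - 1L] + log(up) - log(down)
  }
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  names(p) <- states
  p
}
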