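test_that("SSA paths conserve mass and are reproducible by seed", {
  sys <- cam_system(volume = 0.05)
  p <- ssa_simulate(sys, t_end = 200, seed = 42)
  X <- p$states[, "X"]
  Z <- p$states[, "Z.CaM"]
  Y <- p$states[, "Y.CaM"]
  expect_true(all(p$states >= 0))
  expect_true(all(diff(p$times) > 0))
  expect_equal(unique(X + Z), (X + Z)[1])        # total calcium conserved
  expect_equal(unique(Y + Z), (Y + Z)[1])        # total buffer conserved
  # consecutive states differ by one reaction's +/-1 stoichiometry
  expect_true(all(abs(diff(X)) == 1))

  p2 <- ssa_simulate(sys, t_end = 200, seed = 42)
  expect_identical(p$times, p2$times)
  expect_identical(p$states, p2$states)
  p3 <- ssa_simulate(sys, t_end = 200, seed = 43)
  expect_false(identical(p$times, p3$times))
})

test_that("SSA with diffusion exchanges calcium with the constant pool", {
  sys <- cam_system(volume = 0.05, D_Ca = 0.2)
  p <- ssa_simulate(sys, t_end = 200, seed = 1)
  X <- p$states[, "X"]
  Z <- p$states[, "Z.CaM"]
  expect_gt(length(unique(X + Z)), 1)            # no longer conserved
  expect_equal(unique(p$states[, "Y.CaM"] + Z),
               (p$states[, "Y.CaM"] + Z)[1])     # buffer still conserved
  expect_true(all(X >= 0))
})

test_that("SSA long-run time average agrees with the master-equation mean", {
  sys <- cam_system(volume = 0.02)  # ~60 bound / 1.2 free calcium counts
  p_cme <- cme_stationary(sys)
  m <- distribution_moments(p_cme)
  path <- ssa_simulate(sys, t_end = 4e4, seed = 7)
  occ <- state_occupancy(path, t_burn = 100)
  m_hat <- distribution_moments(occ)
  # standard error of the time average of an exponentially correlated series
  tau <- tau_theory(sys)
  se <- sqrt(m$var * 2 * tau / (4e4 - 100))
  expect_lt(abs(m_hat$mean - m$mean), 3 * se)
})

test_that("resampling interpolates jump paths onto a uniform grid", {
  # hand-built two-event path: X goes 0 -> 2 between t=0 and t=1
  path <- structure(list(
    times = c(0, 1),
    states = cbind(X = c(0, 2)),
    meta = list(engine = "ssa", seed = NULL, t_end = 1, n_events = 1)),
    class = "jump_path")
  tr <- resample_path(path, dt = 0.5)
  expect_equal(tr$values[, "X"], c(0, 1, 2))     # linear midpoint
  trh <- resample_path(path, dt = 0.5, method = "hold")
  expect_equal(trh$values[, "X"], c(0, 0, 2))    # zero-order hold

  sys <- cam_system(volume = 0.05)
  p <- ssa_simulate(sys, t_end = 50, seed = 5)
  tr2 <- resample_path(p, dt = 0.01)
  t_last <- p$times[length(p$times)]
  expect_length(tr2$time, floor(t_last / 0.01) + 1)
  expect_error(resample_path(p, dt = 0), "positive")
})

test_that("noiseless CLE equals the Euler-integrated mass-action ODE", {
  sys <- cam_system(volume = 0.125)
  dt <- 0.01; n <- 400
  tr <- cle_simulate(sys, dt = dt, t_end = n * dt, x0 = 1.0, noise = FALSE)
  # independent Euler oracle in concentration-free count units
  r <- stochastic_rates(sys)
  eq <- equilibrium_state(sys)
  X <- concentration_to_count(1.0, sys$volume)
  Z <- unname(eq$counts$z_eq)
  yT <- unname(eq$counts$y_eq + eq$counts$z_eq)
  ora <- numeric(n + 1); ora[1] <- X
  for (k in seq_len(n)) {
    flux <- (-r$c_plus[[1]] * X * (yT - Z) + r$c_minus[[1]] * Z) * dt
    X <- X + flux; Z <- Z - flux
    ora[k + 1] <- X
  }
  expect_equal(unname(tr$values[, "X"]), ora, tolerance = 1e-12)
})

test_that("CLE trajectories are seed-reproducible, finite, and near theory", {
  sys <- cam_system(volume = 0.125)
  a <- cle_simulate(sys, t_end = 300, seed = 9)
  b <- cle_simulate(sys, t_end = 300, seed = 9)
  expect_identical(a$values, b$values)
  expect_true(all(is.finite(a$values)))
  expect_true(is.numeric(a$meta$n_clamp_species))
  expect_error(cle_simulate(sys, dt = -1, t_end = 10), "positive")

  np <- noise_params(sys)
  tr <- cle_simulate(sys, t_end = 1e4, seed = 2)
  v <- var(tr$values[, "X"])
  expect_lt(abs(v / np$variance - 1), 0.2)
})

test_that("EBA-reduced CLE relaxes like the closed-form solution", {
  sys <- cam_system(volume = 0.125)
  dt <- 0.001
  tr <- cle_eba_simulate(sys, dt = dt, t_end = 4, x0 = 1.0, noise = FALSE)
  # closed-form oracle: mono-exponential decay at rate K1 toward the
  # EBA equilibrium of the perturbed totals (x_T gains the extra calcium)
  K1 <- linear_kinetics(sys)$K1
  x_T <- 1.0 + unname(equilibrium_state(sys)$z_eq)
  x_star <- 0.038 * x_T / K1
  expected <- concentration_to_count(
    (1.0 - x_star) * exp(-K1 * tr$time) + x_star, sys$volume)
  expect_equal(unname(tr$values[, "X"]), expected, tolerance = 1e-2)
  # stationary mean within 3 SE of the equilibrium count (V = 1 fl keeps
  # counts high enough that zero-clamping never biases the mean)
  sys1 <- cam_system(volume = 1)
  np <- noise_params(sys1)
  tr2 <- cle_eba_simulate(sys1, t_end = 5e3, seed = 3)
  se <- sqrt(np$variance * 2 * np$tau / 5e3)
  expect_lt(abs(mean(tr2$values[, "X"]) - np$mu), 3 * se)
})

test_that("noiseless exact OU decays exponentially to machine precision", {
  np <- make_noise_params(mu = 10, tau = 0.5, sigma = 0)
  tr <- oup_simulate(np, x0 = 20, dt = 0.01, t_end = 5, exact = TRUE)
  expect_equal(unname(tr$values[, "X"]),
               10 + 10 * exp(-tr$time / 0.5), tolerance = 1e-12)
})

test_that("exact OU sampling reproduces stationary variance and ACF", {
  np <- make_noise_params(mu = 7.53, tau = 0.516, sigma = 5.35)
  tr <- oup_simulate(np, dt = 0.01, t_end = 2000 * np$tau, seed = 11,
                     exact = TRUE)
  x <- tr$values[, "X"]
  expect_lt(abs(var(x) / np$variance - 1), 0.1)
  a <- autocorrelation(tr, max_lag = 2)
  i <- which.min(abs(a$lags - np$tau))
  expect_lt(abs(a$values[i] - exp(-1)), 0.05)
  # mean within 3 SE
  se <- sqrt(np$variance * 2 * np$tau / (2000 * np$tau))
  expect_lt(abs(mean(x) - np$mu), 3 * se)
  expect_error(oup_simulate(np, dt = 0, t_end = 1), "positive")
  expect_error(oup_simulate(make_noise_params(0, 1, 1), dt = 0.01,
                            t_end = -1), "positive")
})

test_that("Euler and exact OU schemes agree for small dt/tau", {
  np <- make_noise_params(mu = 0, tau = 5, sigma = 1)
  eu <- oup_simulate(np, dt = 0.01, t_end = 5e3, seed = 4)
  ex <- oup_simulate(np, dt = 0.01, t_end = 5e3, seed = 4, exact = TRUE)
  expect_lt(abs(var(eu$values[, "X"]) / var(ex$values[, "X"]) - 1), 0.1)
})

test_that("all four engines agree on the stationary correlation time", {
  sys <- cam_system(volume = 0.125)
  np <- noise_params(sys)
  engines <- c("ssa", "cle", "cle-eba", "oup")
  for (e in engines) {
    est <- vapply(1:3, function(s) {
      tr <- simulate(sys, engine = e, t_end = 4e3, dt = 0.01, seed = s)
      estimate_tau(autocorrelation(tr, max_lag = 3))
    }, numeric(1))
    expect_lt(abs(mean(est) / np$tau - 1), 0.15)
  }
})

test_that("trajectories round-trip through TSV files", {
  sys <- cam_system(volume = 0.125)
  tr <- simulate(sys, engine = "cle", t_end = 5, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$values[, "X"], tr$values[, "X"], tolerance = 1e-6)
  expect_equal(back$meta$engine, "cle")
  unlink(f)
})
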