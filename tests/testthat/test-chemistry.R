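test_that("buffer table lookup returns tabulated kinetics with derived K_D", {
  cam <- buffer_from_table("CaM")
  expect_equal(cam$B_T, 24)
  expect_equal(cam$k_plus, 0.1)
  expect_equal(cam$k_minus, 0.038)
  expect_equal(cam$K_D, 0.038 / 0.1)

  ogb <- buffer_from_table("ogb-5n")  # case-insensitive
  expect_equal(ogb$B_T, 100)
  expect_equal(ogb$K_D, 5.6 / 0.17)

  expect_error(buffer_from_table("Calbindin"), "unknown buffer")
  expect_error(buffer_from_table("Calbindin"), "CaM")  # names the fixtures
})

test_that("dissociation constant is k_minus / k_plus with domain checks", {
  expect_equal(dissociation_constant(0.1, 0.038), 0.38)
  expect_equal(dissociation_constant(0.17, 5.6), 5.6 / 0.17)
  expect_equal(dissociation_constant(1, 0), 0)
  expect_error(dissociation_constant(0, 1), "positive")
  expect_error(dissociation_constant(-1, 1), "positive")
  expect_error(dissociation_constant(1, -1), "non-negative")
})

test_that("buffer_spec validates its invariants", {
  expect_error(buffer_spec("x", B_T = -1, k_plus = 1, k_minus = 1), "B_T")
  expect_error(buffer_spec("x", B_T = 1, k_plus = 0, k_minus = 1), "k_plus")
  expect_error(ca_system(list(buffer_from_table("CaM"),
                              buffer_from_table("CaM"))), "unique")
  expect_error(ca_system("CaM", volume = 0), "volume")
  expect_error(ca_system("CaM", ca_eq = -0.1), "ca_eq")
  expect_error(ca_system("CaM", D_Ca = 0), "D_Ca")
})

test_that("equilibrium partitioning follows mass action", {
  eq <- equilibrium_state(cam_system())
  expect_equal(unname(eq$z_eq), 24 / (1 + 0.38 / 0.1))  # 5 uM
  expect_equal(unname(eq$y_eq), 19)
  expect_equal(eq$x_T, 5.1)
  # mass conservation holds exactly as constructed
  expect_identical(unname(eq$y_eq + eq$z_eq), 24)

  two <- ca_system(c("CaM", "EGTA"), ca_eq = 0.1)
  eq2 <- equilibrium_state(two)
  KD_egta <- 0.00094 / 0.0015
  expect_equal(eq2$z_eq[["EGTA"]], 100 / (1 + KD_egta / 0.1))
  expect_equal(eq2$x_T, 0.1 + sum(eq2$z_eq))

  empty <- equilibrium_state(ca_system(ca_eq = 0.1))
  expect_equal(empty$x_T, 0.1)
  expect_length(empty$z_eq, 0)
})

test_that("copy-number conversion uses Avogadro scaling and is linear", {
  expect_equal(concentration_to_count(0.1, 1.0), 60.2214076)
  expect_equal(round(concentration_to_count(0.1, 1.0)), 60)
  expect_equal(concentration_to_count(1, 1), 602.214076)
  expect_equal(concentration_to_count(0, 5), 0)
  expect_error(concentration_to_count(-1, 1), "non-negative")
  expect_error(concentration_to_count(1, 0), "positive")
  # linearity in both arguments
  expect_equal(concentration_to_count(3 * 0.7, 2.5),
               3 * concentration_to_count(0.7, 2.5))
  expect_equal(concentration_to_count(0.7, 2 * 2.5),
               2 * concentration_to_count(0.7, 2.5))
  # round trip
  expect_equal(count_to_concentration(concentration_to_count(0.37, 0.8), 0.8),
               0.37)
})

test_that("stochastic rates scale only the bimolecular channel", {
  r1 <- stochastic_rates(cam_system(volume = 1))
  expect_equal(unname(r1$c_plus), 0.1 / 602.214076)
  expect_equal(unname(r1$c_minus), 0.038)
  expect_equal(r1$c_d, 0)

  r2 <- stochastic_rates(cam_system(volume = 0.125))
  expect_equal(unname(r2$c_minus), 0.038)  # volume-invariant
  expect_equal(unname(r2$c_plus), unname(r1$c_plus) / 0.125)

  rd <- stochastic_rates(ca_system("CaM", volume = 1, ca_eq = 0.1,
                                   D_Ca = 0.2))
  expect_equal(rd$c_d, 0.2)  # L = 1 um at 1 fl
  rd2 <- stochastic_rates(ca_system("CaM", volume = 0.125, ca_eq = 0.1,
                                    D_Ca = 0.2))
  expect_equal(rd2$c_d, 0.2 / 0.25)
})

test_that("detailed balance holds at equilibrium in count units", {
  for (seed in 1:8) {
    sys <- random_system(seed, M = sample(1:3, 1))
    eq <- equilibrium_state(sys)
    r <- stochastic_rates(sys)
    expect_equal(r$c_plus * eq$counts$x_eq * eq$counts$y_eq,
                 r$c_minus * eq$counts$z_eq, tolerance = 1e-9)
  }
})

test_that("total calcium inverts back to the free concentration", {
  # direct example: inverse of the CaM equilibrium
  inv <- totals_to_equilibrium(5.1, "CaM")
  expect_equal(inv$x_eq, 0.1, tolerance = 1e-10)
  # trivial cases
  expect_equal(totals_to_equilibrium(0, "CaM")$x_eq, 0)
  expect_equal(totals_to_equilibrium(3.7, list())$x_eq, 3.7)
  # round trip on random systems
  for (seed in 11:18) {
    sys <- random_system(seed, M = sample(1:3, 1))
    eq <- equilibrium_state(sys)
    back <- totals_to_equilibrium(eq$x_T, sys$buffers)
    expect_equal(back$x_eq, sys$ca_eq, tolerance = 1e-10)
  }
})

test_that("system configs round-trip through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "volume_fl: 0.125",
    "ca_eq_uM: 0.1",
    "D_Ca_um2_per_ms: 0.2",
    "buffers:",
    "  - CaM",
    "  - name: slow",
    "    B_T: 50",
    "    k_plus: 0.01",
    "    k_minus: 0.002"), cfg)
  sys <- read_system_config(cfg)
  expect_s3_class(sys, "ca_system")
  expect_equal(sys$volume, 0.125)
  expect_equal(sys$D_Ca, 0.2)
  expect_length(sys$buffers, 2)
  expect_equal(sys$buffers[[1]]$B_T, 24)  # resolved from the table
  expect_equal(sys$buffers[[2]]$K_D, 0.2)
  unlink(cfg)
})
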