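test_that("checkpoint inhibition factor matches its calibration values", {
  expect_identical(inhibition_factor(0, 5, 1e-18), 1)
  # steady-state occupancy Q/K_TQ = 2 gives the factor 1/3
  expect_equal(inhibition_factor(7.47e-10, 3.654e-9, 1.365e-18), 1 / 3,
               tolerance = 1e-3)
  # doubling PD-L1 doubles the occupancy: 1/(1 + 4)
  expect_equal(inhibition_factor(7.47e-10, 7.308e-9, 1.365e-18), 1 / 5,
               tolerance = 1e-3)
  expect_error(inhibition_factor(-1e-10, 1e-9, 1e-18), "nonnegative")
  expect_error(inhibition_factor(1e-10, 1e-9, 0), "positive")
})

test_that("inhibition factor is strictly decreasing in P and L, equals 1 iff PL = 0", {
  P <- 10^seq(-12, -8, length.out = 9)
  f <- inhibition_factor(P, 3.654e-9, 1.365e-18)
  expect_true(all(diff(f) < 0))
  L <- 10^seq(-11, -7, length.out = 9)
  g <- inhibition_factor(7.47e-10, L, 1.365e-18)
  expect_true(all(diff(g) < 0))
  expect_true(all(f < 1) && all(g < 1))
  expect_identical(inhibition_factor(1e-9, 0, 1e-18), 1)
})

test_that("PD-L1 closure reproduces the calibrated concentration", {
  expect_equal(pdl1_concentration(2e-3, 1e-3, 0.4, 5.22e-7, 0.01), 3.654e-9,
               tolerance = 1e-12)
  expect_identical(pdl1_concentration(0, 0, 0, 5.22e-7, 0.01), 0)
  # tumor PD-L1 switched off
  expect_equal(pdl1_concentration(2e-3, 1e-3, 0.4, 5.22e-7, 0), 1.566e-9,
               tolerance = 1e-12)
})

test_that("reaction terms vanish at the calibrated steady state except net tumor growth", {
  cal <- calibrate_parameters()
  p <- cal$params
  st <- anchor_state()
  r <- reaction_rhs(st, 0, p, dosing_schedule(0, 0))
  # all immune/cytokine/checkpoint balances are exact by construction
  for (nm in c("D", "T1", "T8", "G", "I12", "I2", "P", "A"))
    expect_lt(abs(r[[nm]]), 1e-12)
  # the cancer equation retains the designed net growth lambda0 * C
  expect_equal(r$C, p$lambda0 * st$C, tolerance = 1e-10)
})

test_that("with empty state and no dosing only the GM-CSF background source acts", {
  p <- default_parameters()
  st <- list(D = 0, T1 = 0, T8 = 0, C = 0, G = 0, I12 = 0, I2 = 0, P = 0, A = 0)
  r <- reaction_rhs(st, 5, p, dosing_schedule(0, 0))
  expect_equal(r$G, p$lambda_G)
  for (nm in setdiff(names(r), "G")) expect_identical(r[[nm]], 0)
})

test_that("tumor reaction term matches the hand-computed balance", {
  p <- default_parameters()
  st <- anchor_state()
  r <- reaction_rhs(st, 0, p, dosing_schedule(0, 0))
  hand <- 0.616 * 0.4 * 0.5 - (11.5 * 2e-3 + 46 * 1e-3) * 0.4 - 0.17 * 0.4
  expect_equal(r$C, hand, tolerance = 1e-12)
  expect_equal(hand, 0.069 * 0.4, tolerance = 1e-12)
})

test_that("reaction rates are continuous in time across the dosing ramp", {
  p <- default_parameters()
  d <- dosing_schedule(1e-10, 2e-10)
  st <- anchor_state()
  for (tb in c(30, 33)) {
    lo <- reaction_rhs(st, tb - 1e-8, p, d)
    hi <- reaction_rhs(st, tb + 1e-8, p, d)
    expect_equal(unlist(lo), unlist(hi), tolerance = 1e-6)
  }
})

test_that("PD-1 ratio term degenerates gracefully without T cells", {
  p <- default_parameters()
  st <- anchor_state()
  st$T1 <- 0; st$T8 <- 0; st$P <- 1e-10; st$A <- 1e-9
  r <- reaction_rhs(st, 0, p, dosing_schedule(0, 0))
  expect_equal(r$P, -(p$mu_PA * st$A + max(p$d_T1, p$d_T8)) * st$P)
})

test_that("compiled reaction terms agree with the reference implementation", {
  p <- default_parameters()
  d <- dosing_schedule(1.3e-10, 0.7e-10)
  set.seed(7)
  for (rep in 1:5) {
    st <- list(D = runif(8, 0, 1e-3), T1 = runif(8, 0, 5e-3),
               T8 = runif(8, 0, 3e-3), C = runif(8, 0.2, 0.5),
               G = runif(8, 0, 1e-9), I12 = runif(8, 0, 1e-9),
               I2 = runif(8, 0, 1e-10), P = runif(8, 0, 2e-9),
               A = runif(8, 0, 1e-8))
    t <- runif(1, 0, 40)
    ref <- reaction_rhs(st, t, p, d)
    X <- do.call(cbind, st)
    cpp <- pdvax:::.reaction_cpp(unclass(p), X, t, d$gamma_G, d$gamma_A,
                                 d$t_stop, d$t_zero)
    for (j in seq_along(ref))
      expect_equal(cpp[, j], ref[[j]], tolerance = 1e-12)
  }
})

test_that("velocity closure integrates a constant source to a linear profile", {
  p <- params_off()
  # only cancer growth on, no death: S(r) = lambda_C * C * (1 - C/C_M) constant
  p$lambda_C <- 0.5
  r <- seq(0, 0.02, length.out = 41)
  st <- uniform_state(list(C = 0.4))
  st$C <- rep(0.4, 41)
  u <- compute_velocity(st, r, 0, p, dosing_schedule(0, 0))
  s0 <- 0.5 * 0.4 * (1 - 0.4 / p$C_M)
  expect_equal(u, s0 * r / (3 * p$theta_tot), tolerance = 1e-10)
  expect_identical(u[1], 0)
})

test_that("velocity at the calibrated steady state follows the net-growth closed form", {
  cal <- calibrate_parameters()
  p <- cal$params
  r <- seq(0, 0.01, length.out = 51)
  st <- lapply(anchor_state(), rep, times = 51)
  u <- compute_velocity(st, r, 0, p, dosing_schedule(0, 0))
  # S reduces to the cancer residual lambda0*Cbar; u is linear in r
  expect_equal(u, p$lambda0 * 0.4 * r / (3 * p$theta_tot), tolerance = 1e-8)
})
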