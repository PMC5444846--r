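# printed-value comparisons use the published precision (3 significant
# figures), i.e. a relative tolerance of 5e-3
expect_printed <- function(computed, printed) {
  expect_equal(computed, printed, tolerance = 5e-3)
}

test_that("diffusion scaling law reproduces the tabulated coefficients", {
  expect_printed(diffusion_from_mw(15.5), 9.9956e-2)   # IL-2
  expect_printed(diffusion_from_mw(70), 6.0472e-2)     # IL-12
  expect_printed(diffusion_from_mw(16.2), 9.8495e-2)   # GM-CSF
  expect_printed(diffusion_from_mw(32), 7.85e-2)       # anti-PD-1
  # identity at the VEGF reference and monotone decrease with size
  expect_equal(diffusion_from_mw(24), 8.64e-2, tolerance = 1e-12)
  mw <- seq(5, 200, by = 5)
  expect_true(all(diff(diffusion_from_mw(mw)) < 0))
  expect_error(diffusion_from_mw(0), "positive")
})

test_that("dendritic-cell activation rates solve the steady-state balance", {
  out <- calibrate_dc_rates()
  expect_printed(out$lambda_DC, 0.364)
  expect_printed(out$lambda_DG, 20.02)
  # linearity: doubling the death rate doubles both rates
  a <- default_anchors(); a$d_D <- 0.2
  out2 <- calibrate_dc_rates(a)
  expect_equal(out2$lambda_DC, 2 * out$lambda_DC)
  expect_equal(out2$lambda_DG, 2 * out$lambda_DG)
  # halving the DC steady state halves the HMGB-1 rate
  a <- default_anchors(); a$Dbar <- 2e-4
  expect_printed(calibrate_dc_rates(a)$lambda_DC, 0.182)
})

test_that("T-cell IL-12 activation rates solve their balances", {
  out <- calibrate_t_cell_rates()
  expect_printed(out$lambda_T1I12, 4.66)
  expect_printed(out$lambda_T8I12, 4.15)
  # the inconsistent naive-CD8 density from the derivation text warns
  a <- default_anchors(); a$T_80 <- 5e-5
  expect_warning(calibrate_t_cell_rates(a), "T_80")
  # degenerate balance: IL-2 proliferation alone already sustains T1
  a <- default_anchors()
  a$d_T1 <- a$lambda_T1I2 * 0.5 / 3   # death == proliferation * 1/2 * 1/3
  expect_equal(calibrate_t_cell_rates(a)$lambda_T1I12, 0, tolerance = 1e-12)
})

test_that("growth and killing rates follow the linear-growth anchor", {
  out <- calibrate_growth_and_killing()
  expect_printed(out$lambda_C, 0.616)
  expect_printed(out$eta1, 11.5)
  expect_printed(out$eta8, 46)
  expect_equal(out$eta8, 4 * out$eta1)
  # no net growth: no killing needed, division rate balances death
  a <- default_anchors(); a$lambda0 <- 1e-300  # anchors must stay positive
  out0 <- calibrate_growth_and_killing(a)
  expect_equal(out0$eta1, 0, tolerance = 1e-290)
  expect_equal(out0$lambda_C, 2 * a$d_C, tolerance = 1e-6)
})

test_that("checkpoint expression, normalization and blocking rate are reproduced", {
  out <- calibrate_checkpoint()
  expect_printed(out$rho_P, 2.49e-7)
  expect_printed(out$rho_L, 5.22e-7)
  expect_printed(out$Pbar, 7.47e-10)
  expect_printed(out$Lbar, 3.654e-9)
  expect_printed(out$Kp_TQ, 1.365e-18)
  expect_printed(out$mu_PA, 6.87e6)
  expect_equal(out$Kp_TQ, 0.5 * out$Pbar * out$Lbar)
})

test_that("cytokine sources and degradation follow half-life and balances", {
  out <- calibrate_sources()
  expect_printed(out$d_G, 1.28)
  expect_printed(out$lambda_G, 2.23e-10)
  expect_printed(out$lambda_I12D, 5.18e-7)
  expect_printed(out$lambda_I2T1, 2.82e-8)
  a <- default_anchors(); a$Gbar_no_drug <- 1e-300
  expect_lt(calibrate_sources(a)$lambda_G, 1e-290)
})

test_that("full calibration round-trips through the reaction terms", {
  cal <- calibrate_parameters()
  st <- anchor_state()
  r <- reaction_rhs(st, 0, cal$params, dosing_schedule(0, 0))
  # every balance used in the calibration closes to round-off, relative to
  # the turnover scale of its species
  scales <- list(D = 0.1 * 4e-4, T1 = 0.197 * 2e-3, T8 = 0.18 * 1e-3,
                 G = 1.28 * 1.74e-10, I12 = 1.38 * 1.5e-10,
                 I2 = 2.376 * 2.37e-11, P = 0.197 * 7.47e-10, A = 1)
  for (nm in names(scales))
    expect_lt(abs(r[[nm]]) / scales[[nm]], 1e-10)
  # provenance marks the derived entries
  expect_true(all(c("lambda_DC", "Kp_TQ", "mu_PA") %in%
                    cal$provenance$parameter[cal$provenance$source == "derived"]))
})

test_that("every calibrated parameter matches its published value at printed precision", {
  p <- calibrate_parameters()$params
  printed <- c(lambda_DC = 0.364, lambda_DG = 20.02, lambda_T1I12 = 4.66,
               lambda_T8I12 = 4.15, lambda_C = 0.616, eta1 = 11.5, eta8 = 46,
               mu_PA = 6.87e6, Kp_TQ = 1.365e-18, delta_I2 = 9.9956e-2,
               delta_I12 = 6.0472e-2, delta_G = 9.8495e-2, delta_A = 7.85e-2,
               d_G = 1.28, lambda_G = 2.23e-10, lambda_I12D = 5.18e-7,
               lambda_I2T1 = 2.82e-8, rho_P = 2.49e-7, rho_L = 5.22e-7)
  for (nm in names(printed))
    expect_printed(p[[nm]], printed[[nm]])
})
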