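# shared fixtures: calibration anchor state, reduced parameter sets

# steady-state densities/concentrations used throughout the calibration
anchor_state <- function() {
  list(D = 4e-4, T1 = 2e-3, T8 = 1e-3, C = 0.4,
       G = 1.74e-10, I12 = 1.5e-10, I2 = 2.37e-11,
       P = 7.47e-10, A = 0)
}

# parameters with every coupling, source and death switched off; individual
# pieces are re-enabled per test
params_off <- function() {
  p <- default_parameters()
  off <- c("lambda_DC", "lambda_DG", "lambda_T1I12", "lambda_T1I2",
           "lambda_T8I12", "lambda_T8I2", "lambda_C", "lambda_G",
           "lambda_I12D", "lambda_I2T1", "eta1", "eta8", "mu_PA",
           "sigma0", "d_D", "d_T1", "d_T8", "d_C", "d_G", "d_I12",
           "d_I2", "d_A")
  for (nm in off) p[[nm]] <- 0
  p
}

# uniform state builder for solver tests
uniform_state <- function(values, R0 = 0.01) {
  st <- list(D = 0, T1 = 0, T8 = 0, C = 0, G = 0, I12 = 0, I2 = 0,
             P = 0, A = 0, R0 = R0)
  for (nm in names(values)) st[[nm]] <- values[[nm]]
  st
}

# day-60 radius of the untreated baseline, computed once per test run
control_r60 <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- simulate_tumor()
      val <<- sim$radius[length(sim$radius)]
    }
    val
  }
})

# coarse solver settings for multi-simulation studies (dose maps, PRCC);
# the day-60 radius at these settings agrees with the default-resolution
# run to well under a percent
coarse_settings <- function(...) solver_settings(n_nodes = 60, tau = 0.01, ...)
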