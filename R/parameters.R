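#' Baseline model parameters
#'
#' Returns the full parameter set of the tumor--immune model as a flat named
#' list of class `"tumor_params"`.  Values are the published baseline: cell
#' diffusivities, cytokine/drug diffusivities from the molecular-weight
#' scaling law, activation/production/death rates, half-saturations,
#' checkpoint expression ratios, reservoir densities and the structural
#' constants of the density-sum closure.  Every "estimated" entry can be
#' re-derived from first principles with [calibrate_parameters()].
#'
#' Units: diffusivities cm^2/day; first-order rates 1/day; `lambda_G` in
#' g/cm^3/day; killing rates `eta1`, `eta8` and the blocking rate `mu_PA` in
#' cm^3/g/day; half-saturations and densities in g/cm^3; `Kp_TQ` in g^2/cm^6;
#' `sigma0` in 1/cm; `rho_P`, `rho_L`, `epsilon` dimensionless.
#'
#' `K_D`, `K_T1`, `K_T8` and `lambda0` are steady-state calibration anchors;
#' they are carried here for reference but never enter the dynamical
#' equations.  `tcell_floor` is the numerical floor below which the
#' PD-1-per-T-cell ratio is treated as degenerate.
#'
#' @return A named list of class `"tumor_params"`.
#' @seealso [calibrate_parameters()], [read_params_config()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$lambda_DC
default_parameters <- function() {
  p <- list(
    delta_D   = 8.64e-7,
    delta_T   = 8.64e-7,   # shared by CD4+, CD8+ T cells and PD-1
    delta_C   = 8.64e-7,
    delta_G   = 9.8495e-2,
    delta_I12 = 6.0472e-2,
    delta_I2  = 9.9956e-2,
    delta_A   = 7.85e-2,
    sigma0    = 1,
    lambda_DC    = 0.364,
    lambda_DG    = 20.02,
    lambda_T1I12 = 4.66,
    lambda_T1I2  = 0.25,
    lambda_T8I12 = 4.15,
    lambda_T8I2  = 0.25,
    lambda_C     = 0.616,
    lambda_G     = 2.23e-10,
    lambda_I12D  = 5.18e-7,
    lambda_I2T1  = 2.82e-8,
    eta1  = 11.5,
    eta8  = 46,
    mu_PA = 6.87e6,
    rho_P = 2.49e-7,
    rho_L = 5.22e-7,
    epsilon = 0.01,
    d_D   = 0.1,
    d_T1  = 0.197,
    d_T8  = 0.18,
    d_C   = 0.17,
    d_G   = 1.28,
    d_I12 = 1.38,
    d_I2  = 2.376,
    d_A   = 0.0462,
    K_G   = 1.74e-9,
    K_C   = 0.4,
    K_I12 = 1.5e-10,
    K_I2  = 2.37e-11,
    Kp_TQ = 1.365e-18,
    K_D   = 4e-4,
    K_T1  = 2e-3,
    K_T8  = 1e-3,
    D_0   = 2e-5,
    T_10  = 4e-4,
    T_80  = 2e-4,
    C_M   = 0.8,
    That_1 = 4e-3,
    That_8 = 2e-3,
    theta_tot = 0.4034,
    lambda0   = 0.069,
    tcell_floor = 1e-12
  )
  class(p) <- "tumor_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: presence of all
#' fields, strict positivity of rates/half-saturations/densities,
#' `epsilon` within \[0, 0.01\], carrying capacity above the tumor
#' half-saturation, and the assumed 2:1 CD4:CD8 ratio of the lymph-node
#' reservoir densities.
#'
#' @param params object of class `"tumor_params"`.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  need <- names(default_parameters_skeleton())
  miss <- setdiff(need, names(params))
  if (length(miss) > 0)
    stop("missing parameters: ", paste(miss, collapse = ", "))
  # structural constants must be strictly positive; rate constants may be
  # switched off (zero) for reduced models and degenerate-limit checks
  strict <- c("delta_D", "delta_T", "delta_C", "delta_G", "delta_I12",
              "delta_I2", "delta_A", "K_G", "K_C", "K_I12", "K_I2", "Kp_TQ",
              "K_D", "K_T1", "K_T8", "D_0", "T_10", "T_80", "C_M",
              "theta_tot", "tcell_floor")
  for (nm in need) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative")
    if (nm %in% strict && v <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  }
  if (params$epsilon < 0 || params$epsilon > 0.01)
    stop("epsilon must lie in [0, 0.01]")
  if (params$C_M <= params$K_C)
    stop("carrying capacity C_M must exceed the tumor half-saturation K_C")
  if (abs(params$That_1 - 2 * params$That_8) > 1e-12 * params$That_1)
    warning("lymph-node T-cell densities deviate from the assumed 2:1 CD4:CD8 ratio")
  invisible(params)
}

# canonical field names checked by validate_parameters
default_parameters_skeleton <- function() {
  list(
    delta_D = 1, delta_T = 1, delta_C = 1, delta_G = 1, delta_I12 = 1,
    delta_I2 = 1, delta_A = 1, sigma0 = 1, lambda_DC = 1, lambda_DG = 1,
    lambda_T1I12 = 1, lambda_T1I2 = 1, lambda_T8I12 = 1, lambda_T8I2 = 1,
    lambda_C = 1, lambda_G = 1, lambda_I12D = 1, lambda_I2T1 = 1, eta1 = 1,
    eta8 = 1, mu_PA = 1, rho_P = 1, rho_L = 1, epsilon = 0.01, d_D = 1,
    d_T1 = 1, d_T8 = 1, d_C = 1, d_G = 1, d_I12 = 1, d_I2 = 1, d_A = 1,
    K_G = 1, K_C = 1, K_I12 = 1, K_I2 = 1, Kp_TQ = 1, K_D = 1, K_T1 = 1,
    K_T8 = 1, D_0 = 1, T_10 = 1, T_80 = 1, C_M = 2, That_1 = 2, That_8 = 1,
    theta_tot = 1, lambda0 = 1, tcell_floor = 1
  )
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("Tumor-immune model parameters (", length(x), " fields)\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(format(df, digits = 5))
  invisible(x)
}

#' Dosing schedule for GVAX and anti-PD-1
#'
#' Both drugs are given every 3 days for 30 days; on the model's time scale
#' this is a constant effective source `gamma` up to `t_stop = 30` days,
#' a linear ramp to zero on `(t_stop, t_zero = 33]`, and zero afterwards.
#'
#' @param gamma_G effective GM-CSF source strength of the vaccine
#'   (g/cm^3/day).
#' @param gamma_A effective anti-PD-1 source strength (g/cm^3/day).
#' @param t_stop day the injections stop (default 30).
#' @param t_zero day the residual source reaches zero (default 33).
#' @return Object of class `"dosing_schedule"`.
#' @export
#' @examples
#' dosing_schedule(1e-10, 2e-10)
dosing_schedule <- function(gamma_G = 0, gamma_A = 0, t_stop = 30, t_zero = 33) {
  stopifnot(gamma_G >= 0, gamma_A >= 0, t_stop > 0, t_zero > t_stop)
  structure(list(gamma_G = gamma_G, gamma_A = gamma_A,
                 t_stop = t_stop, t_zero = t_zero),
            class = "dosing_schedule")
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat(sprintf("Dosing: gamma_G = %.3g, gamma_A = %.3g g/cm3/day; on [0, %g], ramp to 0 at day %g\n",
              x$gamma_G, x$gamma_A, x$t_stop, x$t_zero))
  invisible(x)
}

#' Time course of an effective drug source
#'
#' Piecewise source: `gamma` for `t <= t_stop`, linear ramp
#' `gamma * (t_zero - t)/(t_zero - t_stop)` for `t_stop < t <= t_zero`,
#' zero after `t_zero`.  Continuous on `[0, Inf)`.
#'
#' @param t time in days (vectorized); must be nonnegative.
#' @param gamma plateau source strength (g/cm^3/day).
#' @param schedule a [dosing_schedule()]; only its `t_stop`/`t_zero` are used.
#' @return Source strength at `t`, same length as `t`.
#' @export
#' @examples
#' s <- dosing_schedule()
#' source_schedule(c(10, 31.5, 40), 1e-10, s)
source_schedule <- function(t, gamma, schedule = dosing_schedule()) {
  if (any(t < 0)) stop("t must be nonnegative")
  out <- numeric(length(t))
  out[t <= schedule$t_stop] <- gamma
  ramp <- t > schedule$t_stop & t <= schedule$t_zero
  out[ramp] <- gamma * (schedule$t_zero - t[ramp]) /
    (schedule$t_zero - schedule$t_stop)
  out
}

#' Default initial state
#'
#' Spatially uniform initial values: cancer density just below its
#' steady state, immune-cell densities above theirs (their sum equals
#' `theta_tot`), cytokines/PD-1 near the calibrated steady states, no drug,
#' and an initial tumor radius of 0.01 cm.
#'
#' @param params model parameters (used only for consistency checking).
#' @param P0 initial PD-1 concentration.  The published value `11.2e-10`
#'   g/cm^3 is retained as the default even though `rho_P * (T1 + T8)` at the
#'   initial densities gives `14.94e-10`; the initial state is only required
#'   to be near steady state, and the value is exposed here for exploration.
#' @param R0 initial tumor radius (cm).
#' @return Named list with one scalar per species plus `R0`.
#' @export
default_initial_state <- function(params = default_parameters(),
                                  P0 = 11.2e-10, R0 = 0.01) {
  init <- list(D = 6e-4, T1 = 4e-3, T8 = 2e-3, C = 0.3968,
               G = 2.61e-10, I12 = 1.8e-10, I2 = 4.74e-11,
               P = P0, A = 0, R0 = R0)
  tot <- init$D + init$T1 + init$T8 + init$C
  if (abs(tot - params$theta_tot) > 1e-10)
    warning("initial cell densities do not sum to theta_tot")
  init
}

#' Read model parameters from a YAML config file
#'
#' The config is a flat key-to-value mapping with the field names of
#' [default_parameters()].  The bundled default,
#' `system.file("extdata", "default_params.yaml", package = "pdvax")`,
#' reproduces the baseline table exactly.
#'
#' @param path path to a YAML file.
#' @return A validated `"tumor_params"` list.
#' @export
read_params_config <- function(path) {
  p <- yaml::read_yaml(path)
  p <- lapply(p, as.numeric)
  class(p) <- "tumor_params"
  validate_parameters(p)
  p
}

#' Write model parameters to a YAML config file
#'
#' @param params a `"tumor_params"` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  validate_parameters(params)
  yaml::write_yaml(lapply(unclass(params), function(v) v), path,
                   precision = 12)
  invisible(path)
}
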