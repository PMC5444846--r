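#' Solver settings
#'
#' Numerical controls for the moving-mesh integrator.  Defaults: 100 mesh
#' intervals, time step 5e-3 day, Picard tolerance 1e-8 (relative, per
#' species) with at most 50 inner iterations, remeshing to a uniform grid
#' whenever adjacent spacings differ by more than a factor 2, and up to 8
#' recursive step halvings on a failed step.
#'
#' @param n_nodes number of mesh intervals (nodes are `n_nodes + 1`); at
#'   least 16.
#' @param tau time step (day).
#' @param t_end end time (day).
#' @param out_every output cadence (day).
#' @param picard_tol relative convergence tolerance of the Picard loop.
#' @param picard_max maximum Picard iterations per step.
#' @param remesh_ratio adjacent-spacing ratio that triggers remeshing.
#' @param max_halvings recursive step halvings before a hard error.
#' @param r_elim elimination radius (cm): when the free boundary falls below
#'   this value the tumor is considered eliminated and the state is frozen
#'   for the rest of the run (set to 0 to disable).  The default 1e-3 cm is
#'   a single cell diameter: below it the continuum description (and the
#'   free-boundary formulation, whose surface influx per unit volume
#'   diverges as `R -> 0`) is meaningless.  A step that fails to converge
#'   while `R <= 2 * r_elim` is interpreted as the terminal collapse of an
#'   eliminated tumor.
#' @return Object of class `"solver_settings"`.
#' @export
solver_settings <- function(n_nodes = 100, tau = 5e-3, t_end = 60,
                            out_every = 0.25, picard_tol = 1e-8,
                            picard_max = 50, remesh_ratio = 2,
                            max_halvings = 8, r_elim = 1e-3) {
  stopifnot(n_nodes >= 16, tau > 0, t_end > 0, out_every >= tau,
            picard_tol > 0, picard_max >= 1, remesh_ratio > 1,
            max_halvings >= 0, r_elim >= 0)
  structure(list(n_nodes = as.integer(n_nodes), tau = tau, t_end = t_end,
                 out_every = out_every, picard_tol = picard_tol,
                 picard_max = as.integer(picard_max),
                 remesh_ratio = remesh_ratio,
                 max_halvings = as.integer(max_halvings), r_elim = r_elim),
            class = "solver_settings")
}

# build the (n+1) x 9 state matrix the compiled solver expects
.state_matrix <- function(init, n_nodes) {
  sp <- .species_names()
  X <- matrix(0, nrow = n_nodes + 1, ncol = length(sp),
              dimnames = list(NULL, sp))
  for (s in sp) {
    v <- init[[s]]
    if (is.null(v)) stop("initial state is missing species ", s)
    X[, s] <- rep_len(v, n_nodes + 1)
  }
  X
}

.par_for_cpp <- function(params) {
  validate_parameters(params)
  unclass(params)
}

#' Simulate the free-boundary tumor model
#'
#' Integrates the coupled reaction--advection--diffusion system on the
#' moving radial mesh with the fully implicit scheme: each step runs a
#' Picard loop (velocity from the current iterate, one nonuniform-grid
#' tridiagonal solve per species, iterate to tolerance), then moves the
#' nodes with the converged velocity and the free boundary by
#' `R' = u(R)`.  T cells obey a Robin influx condition at `r = R` with flux
#' coefficient `sigma0 * I12/(I12 + K_I12)`; all other species are no-flux;
#' all fields are symmetric at `r = 0`.
#'
#' @param params model parameters, see [default_parameters()].
#' @param dosing a [dosing_schedule()]; the control run uses
#'   `dosing_schedule(0, 0)`.
#' @param settings numerical controls, see [solver_settings()].
#' @param init initial condition: a named list of species scalars (uniform
#'   profiles) or vectors of length `n_nodes + 1`, plus the initial radius
#'   `R0`; defaults to [default_initial_state()].
#' @return Object of class `"tumor_sim"`: `time`, `radius`, `volume`
#'   (cm^3, `4/3 pi R^3`), `avg` (matrix of volume-averaged
#'   densities/concentrations, one column per species), `cons_dev`
#'   (relative deviation of `D+T1+T8+C` from `theta_tot` at each output
#'   time), final profiles in `$final`, and solver diagnostics in
#'   `$diagnostics`.
#' @export
#' @examples
#' \donttest{
#' ctrl <- simulate_tumor(settings = solver_settings(n_nodes = 40, tau = 0.02))
#' tail(ctrl$radius, 1)
#' }
simulate_tumor <- function(params = default_parameters(),
                           dosing = dosing_schedule(),
                           settings = solver_settings(),
                           init = default_initial_state(params)) {
  stopifnot(inherits(settings, "solver_settings"),
            inherits(dosing, "dosing_schedule"))
  R0 <- init$R0
  if (is.null(R0) || R0 <= 0) stop("init$R0 must be a positive radius")
  n <- settings$n_nodes
  r0 <- seq(0, R0, length.out = n + 1)
  X0 <- .state_matrix(init, n)
  out <- .run_sim_cpp(.par_for_cpp(params), dosing$gamma_G, dosing$gamma_A,
                      dosing$t_stop, dosing$t_zero, r0, X0,
                      0, settings$t_end, settings$tau, settings$out_every,
                      settings$picard_tol, settings$picard_max,
                      settings$remesh_ratio, settings$max_halvings,
                      settings$r_elim)
  sp <- .species_names()
  avg <- out$avg
  colnames(avg) <- sp
  Xf <- out$X_final
  colnames(Xf) <- sp
  if (out$clips > 0)
    warning(sprintf("%d negative round-off values were clipped to 0", out$clips))
  structure(list(
    time = out$time, radius = out$radius,
    volume = 4 / 3 * pi * out$radius^3,
    avg = avg, cons_dev = out$cons_dev,
    final = list(r = out$r_final, profiles = Xf),
    eliminated = isTRUE(out$eliminated),
    diagnostics = list(max_cons_dev = out$max_cons_dev,
                       picard_iters = out$picard_iters, steps = out$steps,
                       clips = out$clips, remeshes = out$remeshes,
                       halvings = out$halvings),
    params = params, dosing = dosing, settings = settings
  ), class = "tumor_sim")
}

#' Advance the state by one implicit time step
#'
#' Exposes a single step of the moving-mesh scheme for testing and for
#' custom time loops: identical code path as [simulate_tumor()].
#'
#' @param state named list of species vectors on `mesh`.
#' @param mesh node positions (strictly increasing, starting at 0).
#' @param t current time (day).
#' @param tau step size (day).
#' @param params,dosing,settings as in [simulate_tumor()].
#' @return List with the updated `state`, `mesh` and `t`.
#' @export
advance_step <- function(state, mesh, t, tau, params = default_parameters(),
                         dosing = dosing_schedule(),
                         settings = solver_settings()) {
  n <- length(mesh) - 1
  X0 <- .state_matrix(state, n)
  out <- .run_sim_cpp(.par_for_cpp(params), dosing$gamma_G, dosing$gamma_A,
                      dosing$t_stop, dosing$t_zero, mesh, X0,
                      t, t + tau, tau, tau,
                      settings$picard_tol, settings$picard_max,
                      settings$remesh_ratio, settings$max_halvings, 0)
  Xf <- out$X_final
  newstate <- lapply(seq_along(.species_names()), function(s) Xf[, s])
  names(newstate) <- .species_names()
  list(state = newstate, mesh = as.numeric(out$r_final), t = t + tau)
}

#' @export
print.tumor_sim <- function(x, ...) {
  nt <- length(x$time)
  cat(sprintf("Tumor simulation: t in [%g, %g] days, R: %.4g -> %.4g cm\n",
              x$time[1], x$time[nt], x$radius[1], x$radius[nt]))
  cat(sprintf("  dosing gamma_G = %.3g, gamma_A = %.3g g/cm3/day\n",
              x$dosing$gamma_G, x$dosing$gamma_A))
  cat(sprintf("  mesh %d+1 nodes, tau = %g day; max |D+T1+T8+C - theta|/theta = %.2e\n",
              x$settings$n_nodes, x$settings$tau, x$diagnostics$max_cons_dev))
  invisible(x)
}

#' @export
summary.tumor_sim <- function(object, ...) {
  nt <- length(object$time)
  cat(sprintf("Final state at day %g:\n", object$time[nt]))
  cat(sprintf("  R = %.4g cm, volume = %.4g cm3\n",
              object$radius[nt], object$volume[nt]))
  cat("  volume-averaged densities/concentrations (g/cm3):\n")
  print(signif(object$avg[nt, ], 4))
  invisible(object)
}

#' Plot a simulation
#'
#' Panels for the tumor radius and the volume-averaged cell densities and
#' cytokine/drug concentrations over time.
#'
#' @param x a `"tumor_sim"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tumor_sim <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$time, x$radius, type = "l", xlab = "day", ylab = "R(t) [cm]",
       main = "tumor radius")
  plot(x$time, x$avg[, "C"], type = "l", xlab = "day", ylab = "g/cm3",
       main = "cancer cells (avg)")
  matplot(x$time, x$avg[, c("D", "T1", "T8")], type = "l", lty = 1,
          xlab = "day", ylab = "g/cm3", main = "immune cells (avg)", ...)
  legend("topright", c("D", "T1", "T8"), col = 1:3, lty = 1, bty = "n")
  matplot(x$time, x$avg[, c("G", "I12", "I2", "P", "A")], type = "l", lty = 1,
          xlab = "day", ylab = "g/cm3", main = "cytokines & drugs (avg)", ...)
  legend("topright", c("G", "I12", "I2", "P", "A"), col = 1:5, lty = 1,
         bty = "n")
  invisible(x)
}

#' Write a simulation to CSV
#'
#' Long header: `t`, `R`, `volume`, then one column per species average.
#'
#' @param sim a `"tumor_sim"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  df <- data.frame(t = sim$time, R = sim$radius, volume = sim$volume,
                   sim$avg, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
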