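test_that("a state with all rates off is a fixed point of the step", {
  p <- params_off()
  st <- uniform_state(list(D = 1e-4, T1 = 1e-3, T8 = 5e-4, C = 0.4,
                           G = 1e-10, I12 = 1e-10, I2 = 1e-11,
                           P = 5e-10, A = 1e-9))
  mesh <- seq(0, 0.01, length.out = 41)
  out <- advance_step(st, mesh, 0, 0.01, p, dosing_schedule(0, 0))
  for (nm in names(out$state))
    expect_equal(out$state[[nm]], rep(st[[nm]], 41), tolerance = 1e-12)
  expect_equal(out$mesh, mesh, tolerance = 1e-14)
})

test_that("pure decay reproduces the implicit-Euler closed form in one step", {
  p <- params_off()
  p$d_G <- 1.3
  p$d_I2 <- 0.4
  tau <- 0.05
  st <- uniform_state(list(G = 2e-10, I2 = 5e-11))
  mesh <- seq(0, 0.01, length.out = 33)
  out <- advance_step(st, mesh, 0, tau, p, dosing_schedule(0, 0))
  # exact up to round-off in the (uniform) diffusion stencil cancellation
  expect_equal(out$state$G, rep(2e-10 / (1 + 1.3 * tau), 33), tolerance = 1e-9)
  expect_equal(out$state$I2, rep(5e-11 / (1 + 0.4 * tau), 33), tolerance = 1e-9)
  # untouched species remain untouched
  expect_equal(out$state$C, rep(0, 33))
})

test_that("uniform logistic growth matches the closed-form solution", {
  # immune and cytokine couplings off; a huge total-density constant turns
  # the velocity off so the tumor equation reduces to logistic-with-death
  p <- params_off()
  p$lambda_C <- 0.616
  p$d_C <- 0.17
  p$theta_tot <- 1e6
  C0 <- 0.3968
  st <- uniform_state(list(C = C0))
  sim <- simulate_tumor(p, dosing_schedule(0, 0),
                        solver_settings(n_nodes = 24, tau = 2e-4, t_end = 5,
                                        out_every = 0.5),
                        init = st)
  r <- p$lambda_C - p$d_C
  K <- p$C_M * r / p$lambda_C
  tt <- sim$time
  exact <- K * C0 * exp(r * tt) / (K + C0 * (exp(r * tt) - 1))
  expect_lt(max(abs(sim$avg[, "C"] - exact) / exact), 1e-3)
  # no velocity: radius must not move
  expect_equal(sim$radius, rep(0.01, length(tt)), tolerance = 1e-6)
})

test_that("control run conserves total cell density and shows the expected shapes", {
  sim <- simulate_tumor()
  expect_lt(sim$diagnostics$max_cons_dev, 1e-3)
  expect_equal(sim$diagnostics$clips, 0)
  expect_false(sim$eliminated)
  # radius grows monotonically
  expect_true(all(diff(sim$radius) > 0))
  # cancer average rises then flattens; immune averages fall then flatten
  nt <- length(sim$time)
  half <- which.min(abs(sim$time - 30))
  expect_gt(sim$avg[half, "C"], sim$avg[1, "C"])
  late_slope <- function(nm) {
    v <- sim$avg[, nm]
    (v[nt] - v[half]) / (sim$time[nt] - sim$time[half])
  }
  expect_lt(abs(late_slope("C")) / sim$avg[nt, "C"], 5e-3)
  for (nm in c("D", "T1", "T8", "I12", "I2")) {
    expect_lt(sim$avg[half, nm], sim$avg[1, nm])
    expect_lt(abs(late_slope(nm)) / sim$avg[nt, nm], 1e-2)
  }
  # volume identity
  expect_equal(sim$volume, 4 / 3 * pi * sim$radius^3)
})

test_that("radius self-converges under mesh and step refinement", {
  r1 <- control_r60()
  sim2 <- simulate_tumor(settings = solver_settings(n_nodes = 150,
                                                    tau = 2.5e-3))
  r2 <- sim2$radius[length(sim2$radius)]
  expect_lt(abs(r1 - r2) / r2, 5e-3)
})

test_that("without anti-PD-1 dosing the drug field stays identically zero", {
  sim <- simulate_tumor(dosing = dosing_schedule(1e-10, 0),
                        settings = coarse_settings(t_end = 10))
  expect_true(all(sim$avg[, "A"] == 0))
  expect_true(all(sim$final$profiles[, "A"] == 0))
})

test_that("one advance_step equals a single-step simulation", {
  p <- default_parameters()
  init <- default_initial_state(p)
  n <- 40
  mesh <- seq(0, init$R0, length.out = n + 1)
  st <- init[setdiff(names(init), "R0")]
  out <- advance_step(st, mesh, 0, 5e-3, p, dosing_schedule(1e-10, 1e-10),
                      solver_settings(n_nodes = n))
  sim <- simulate_tumor(p, dosing_schedule(1e-10, 1e-10),
                        solver_settings(n_nodes = n, tau = 5e-3, t_end = 5e-3,
                                        out_every = 5e-3))
  expect_equal(out$state$C, unname(sim$final$profiles[, "C"]), tolerance = 1e-12)
  expect_equal(out$mesh[n + 1], sim$radius[length(sim$radius)], tolerance = 1e-12)
})

test_that("T-cell influx through the boundary raises the near-boundary profile", {
  # strengthen the flux coefficient so the rim is visible over the rather
  # small cell diffusivity
  p <- default_parameters()
  p$sigma0 <- 100
  sim <- simulate_tumor(p, settings = coarse_settings(t_end = 20))
  prof <- sim$final$profiles
  n <- nrow(prof)
  expect_gt(prof[n, "T1"], prof[1, "T1"])
  expect_gt(prof[n, "T8"], prof[1, "T8"])
  # the influx carries total cell mass in with it, so the density-sum
  # constraint relaxes slightly in the rim; it must stay within tolerance
  expect_lt(sim$diagnostics$max_cons_dev, 2e-3)
})

test_that("strong treatment can eliminate the tumor, freezing the state", {
  p <- default_parameters()
  # double the killing rates and relieve the checkpoint strongly
  p$eta1 <- 40; p$eta8 <- 160
  sim <- simulate_tumor(p, dosing_schedule(4.8e-10, 4e-10),
                        settings = coarse_settings())
  expect_true(sim$eliminated)
  nt <- length(sim$time)
  expect_lte(sim$radius[nt], 2e-3 + 1e-6)
  # schedule still reaches day 60
  expect_equal(sim$time[nt], 60)
})

test_that("PDE solver matches an independent ODE oracle in the uniform limit", {
  # with near-uniform fields the model reduces to ODEs for the averages:
  # advected species are diluted by the volumetric growth rate phi = S/theta
  # and the radius obeys R' = phi R / 3; deSolve integrates this reduction
  # independently of the finite-difference machinery
  p <- default_parameters()
  dos <- dosing_schedule(1e-10, 1e-10)
  rhs <- function(t, y, ...) {
    y <- pmax(y, 0)   # guard the integrator's trial excursions
    names(y) <- c("D", "T1", "T8", "C", "G", "I12", "I2", "P", "A", "R")
    st <- as.list(y[1:9])
    f <- unlist(reaction_rhs(st, t, p, dos))
    phi <- (f["D"] + f["T1"] + f["T8"] + f["C"]) / p$theta_tot
    for (nm in c("D", "T1", "T8", "C", "P")) f[nm] <- f[nm] - phi * y[nm]
    list(unname(c(f, phi * y[10] / 3)))
  }
  init <- default_initial_state(p)
  y0 <- c(init$D, init$T1, init$T8, init$C, init$G, init$I12, init$I2,
          init$P, init$A, init$R0)
  ode <- deSolve::lsoda(y0, c(0, 10), rhs, rtol = 1e-8, atol = 1e-20)
  sim <- simulate_tumor(p, dos, solver_settings(t_end = 10))
  nt <- length(sim$time)
  expect_equal(sim$radius[nt], unname(ode[2, 11]), tolerance = 2e-3)
  expect_equal(unname(sim$avg[nt, "T1"]), unname(ode[2, 3]), tolerance = 5e-3)
  expect_equal(unname(sim$avg[nt, "C"]), unname(ode[2, 5]), tolerance = 1e-3)
  expect_equal(unname(sim$avg[nt, "A"]), unname(ode[2, 10]), tolerance = 5e-3)
})
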