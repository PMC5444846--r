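#' PD-1--PD-L1 inhibition factor
#'
#' The complex formed by PD-1 (`P`) and PD-L1 (`L`) suppresses T-cell
#' activation.  Because complex turnover is fast relative to the cell
#' dynamics, the complex is algebraic, `Q = sigma * P * L`, and the
#' suppression enters every T-cell production term as the factor
#' \deqn{\frac{1}{1 + P L / K'_{TQ}} \in (0, 1],}
#' where `Kp_TQ` absorbs the unknown association/dissociation ratio via the
#' normalization at the calibrated steady state (`Q/K_TQ = 2` there, so the
#' factor equals 1/3).
#'
#' @param P PD-1 concentration (g/cm^3), vectorized.
#' @param L PD-L1 concentration (g/cm^3), vectorized.
#' @param Kp_TQ normalization constant (g^2/cm^6), strictly positive.
#' @return Dimensionless factor in (0, 1]; equals 1 iff `P * L == 0`.
#' @export
#' @examples
#' inhibition_factor(7.47e-10, 3.654e-9, 1.365e-18)  # 1/3 at steady state
inhibition_factor <- function(P, L, Kp_TQ) {
  if (any(P < 0) || any(L < 0)) stop("P and L must be nonnegative")
  if (any(Kp_TQ <= 0)) stop("Kp_TQ must be strictly positive")
  1 / (1 + P * L / Kp_TQ)
}

#' PD-L1 concentration closure
#'
#' PD-L1 sits on activated T cells and (with weight `epsilon`) on tumor
#' cells, so its concentration is algebraic in the cell densities:
#' `L = rho_L * (T1 + T8 + epsilon * C)`.
#'
#' @param T1,T8,C cell densities (g/cm^3), vectorized.
#' @param rho_L PD-L1 mass fraction per T cell (dimensionless).
#' @param epsilon tumor PD-L1 expression relative to T cells, in \[0, 0.01\].
#' @return PD-L1 concentration (g/cm^3).
#' @export
pdl1_concentration <- function(T1, T8, C, rho_L, epsilon) {
  if (any(T1 < 0) || any(T8 < 0) || any(C < 0))
    stop("cell densities must be nonnegative")
  rho_L * (T1 + T8 + epsilon * C)
}

#' PD-1 concentration at the no-drug steady state
#'
#' Without anti-PD-1 the PD-1 concentration is slaved to the T cells,
#' `P = rho_P * (T1 + T8)`.  Under treatment `P` becomes dynamical
#' (see [reaction_rhs()]); this closure is used for calibration and for
#' constructing near-steady initial states.
#'
#' @param T1,T8 T-cell densities (g/cm^3).
#' @param rho_P PD-1 mass fraction per T cell.
#' @return PD-1 concentration (g/cm^3).
#' @export
pd1_concentration <- function(T1, T8, rho_P) {
  rho_P * (T1 + T8)
}

#' Reaction terms of the model equations
#'
#' Evaluates the non-transport (reaction, source, sink) right-hand side of
#' every dynamical equation at one or more spatial nodes.  This is the
#' reference implementation of the model core; the compiled solver evaluates
#' the identical algebra internally.
#'
#' The species and their reaction terms:
#' * `D` (dendritic cells): Michaelis--Menten activation of the immature
#'   reservoir `D_0` by the HMGB-1 proxy (tumor density) and by GM-CSF,
#'   minus death.  The HMGB-1/necrosis chain is folded into the
#'   `C/(K_C + C)` term via its quasi-steady state.
#' * `T1`, `T8` (activated T cells): IL-12 activation of the naive reservoir
#'   plus IL-2-driven proliferation, both damped by the checkpoint factor
#'   [inhibition_factor()], minus death.
#' * `C` (cancer cells): logistic growth minus T-cell killing minus death.
#' * `G`, `I12`, `I2` (cytokines): constant/vaccine source or cellular
#'   production minus degradation.
#' * `P` (PD-1): rides on the T cells -- the per-T-cell ratio `P/(T1+T8)`
#'   multiplies the net T-cell production/death -- minus depletion by the
#'   drug.  If `T1 + T8` falls below `params$tcell_floor` the ratio terms
#'   are dropped and `P` decays at rate `mu_PA * A + max(d_T1, d_T8)`.
#' * `A` (anti-PD-1): dosing source minus consumption in blocking PD-1 minus
#'   degradation.
#'
#' @param state named list of numeric vectors `D, T1, T8, C, G, I12, I2, P, A`
#'   (equal lengths; scalars allowed).
#' @param t time in days (scalar, nonnegative); sets the dosing sources.
#' @param params model parameters, see [default_parameters()].
#' @param dosing a [dosing_schedule()].
#' @return Named list of reaction rates (g/cm^3/day), one vector per species.
#' @export
#' @examples
#' st <- list(D = 4e-4, T1 = 2e-3, T8 = 1e-3, C = 0.4, G = 1.74e-10,
#'            I12 = 1.5e-10, I2 = 2.37e-11, P = 7.47e-10, A = 0)
#' reaction_rhs(st, 0, default_parameters(), dosing_schedule(0, 0))
reaction_rhs <- function(state, t, params = default_parameters(),
                         dosing = dosing_schedule()) {
  if (length(t) != 1 || t < 0) stop("t must be a nonnegative scalar")
  sp <- .species_names()
  miss <- setdiff(sp, names(state))
  if (length(miss) > 0)
    stop("state is missing species: ", paste(miss, collapse = ", "))
  p <- params
  n <- max(lengths(state[sp]))
  st <- lapply(state[sp], rep_len, length.out = n)
  D <- st$D; T1 <- st$T1; T8 <- st$T8; C <- st$C
  G <- st$G; I12 <- st$I12; I2 <- st$I2; P <- st$P; A <- st$A

  Ghat <- source_schedule(t, dosing$gamma_G, dosing)
  Ahat <- source_schedule(t, dosing$gamma_A, dosing)

  f12 <- I12 / (p$K_I12 + I12)
  f2  <- I2 / (p$K_I2 + I2)
  L <- pdl1_concentration(T1, T8, C, p$rho_L, p$epsilon)
  inhib <- inhibition_factor(P, L, p$Kp_TQ)

  rate <- list()
  rate$D <- p$lambda_DC * p$D_0 * C / (p$K_C + C) +
    p$lambda_DG * p$D_0 * G / (p$K_G + G) - p$d_D * D
  rate$T1 <- (p$lambda_T1I12 * p$T_10 * f12 + p$lambda_T1I2 * T1 * f2) * inhib -
    p$d_T1 * T1
  rate$T8 <- (p$lambda_T8I12 * p$T_80 * f12 + p$lambda_T8I2 * T8 * f2) * inhib -
    p$d_T8 * T8
  rate$C <- p$lambda_C * C * (1 - C / p$C_M) -
    (p$eta1 * T1 + p$eta8 * T8) * C - p$d_C * C
  rate$G <- p$lambda_G + Ghat - p$d_G * G
  rate$I12 <- p$lambda_I12D * D - p$d_I12 * I12
  rate$I2 <- p$lambda_I2T1 * T1 - p$d_I2 * I2

  Tsum <- T1 + T8
  prodT <- ((p$lambda_T1I12 * p$T_10 + p$lambda_T8I12 * p$T_80) * f12 +
              (p$lambda_T1I2 * T1 + p$lambda_T8I2 * T8) * f2) * inhib
  deathT <- p$d_T1 * T1 + p$d_T8 * T8
  ok <- Tsum > p$tcell_floor
  rP <- numeric(length(Tsum))
  rP[ok] <- (P[ok] / Tsum[ok]) * (prodT[ok] - deathT[ok]) -
    p$mu_PA * P[ok] * A[ok]
  rP[!ok] <- -(p$mu_PA * A[!ok] + max(p$d_T1, p$d_T8)) * P[!ok]
  rate$P <- rP
  rate$A <- Ahat - p$mu_PA * P * A - p$d_A * A
  rate
}

#' Cell velocity from the density-sum closure
#'
#' The four cell species sum to the constant `theta_tot` everywhere, so the
#' divergence of the common velocity is slaved to the summed cell reaction
#' terms `S(r)`: `theta_tot * div(u) = S`.  Because all cell species share
#' one diffusion coefficient, the diffusion terms cancel in the sum.  In
#' radial symmetry
#' \deqn{u(r) = \frac{1}{\theta_{tot}\, r^2}\int_0^r s^2 S(s)\,ds, \qquad u(0)=0.}
#'
#' @param state named list of species vectors on the mesh (see
#'   [reaction_rhs()]).
#' @param mesh strictly increasing node positions, `mesh[1] == 0`.
#' @param t time in days.
#' @param params,dosing model parameters and dosing schedule.
#' @return Radial velocity (cm/day) at each node.
#' @export
compute_velocity <- function(state, mesh, t, params = default_parameters(),
                             dosing = dosing_schedule()) {
  if (any(diff(mesh) <= 0)) stop("mesh nodes must be strictly increasing")
  rate <- reaction_rhs(state, t, params, dosing)
  S <- rate$D + rate$T1 + rate$T8 + rate$C
  S <- rep_len(S, length(mesh))
  r <- mesh
  n <- length(r)
  # integrate s^2 * (piecewise-linear S) exactly on each interval; the plain
  # trapezoid of s^2 S misbehaves near the origin where s^2 curvature matters
  ra <- r[-n]; rb <- r[-1]; h <- rb - ra
  i3 <- (rb^3 - ra^3) / 3
  i4 <- (rb^4 - ra^4) / 4
  seg <- S[-n] * i3 + (S[-1] - S[-n]) / h * (i4 - ra * i3)
  acc <- cumsum(c(0, seg))
  u <- numeric(n)
  u[-1] <- acc[-1] / (params$theta_tot * r[-1]^2)
  u
}
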