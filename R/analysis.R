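#' Cache for day-60 radii
#'
#' Dose-map construction re-uses simulations across dose pairs (the control
#' run, and the inflated monotherapies shared along rows/columns of a
#' synergy grid).  A cache is an environment keyed by the dose pair; pass
#' the same cache to repeated calls of [efficacy()] / [synergy()] /
#' [dose_map()] with identical `params`/`settings` to avoid recomputation.
#'
#' @return An empty cache environment.
#' @export
new_r60_cache <- function() new.env(parent = emptyenv())

# final-time radius for a dose pair, memoized; also stores final averages
.r60 <- function(gamma_G, gamma_A, params, settings, cache) {
  key <- sprintf("%.12e|%.12e", gamma_G, gamma_A)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  sim <- simulate_tumor(params, dosing_schedule(gamma_G, gamma_A), settings)
  nt <- length(sim$time)
  res <- list(R60 = sim$radius[nt],
              C_avg = unname(sim$avg[nt, "C"]),
              T_avg = unname(sim$avg[nt, "T1"] + sim$avg[nt, "T8"]))
  cache[[key]] <- res
  res
}

#' Treatment efficacy
#'
#' Relative reduction of the day-`t_end` tumor radius versus the untreated
#' control:
#' \deqn{E(\gamma_G, \gamma_A) = \frac{R_{60}(0,0) - R_{60}(\gamma_G,\gamma_A)}{R_{60}(0,0)}.}
#' `E` is 0 for the control, positive when treatment shrinks the tumor, and
#' reaches 1 when the tumor is eliminated by day 60.
#'
#' @param gamma_G,gamma_A effective dose strengths (g/cm^3/day).
#' @param params,settings forwarded to [simulate_tumor()].
#' @param cache optional [new_r60_cache()] for re-use across calls.
#' @return Efficacy (dimensionless, at most 1).
#' @export
efficacy <- function(gamma_G, gamma_A, params = default_parameters(),
                     settings = solver_settings(), cache = new_r60_cache()) {
  ctrl <- .r60(0, 0, params, settings, cache)$R60
  if (ctrl <= 0) stop("degenerate control: R60(0,0) = 0")
  (ctrl - .r60(gamma_G, gamma_A, params, settings, cache)$R60) / ctrl
}

#' Dose synergy
#'
#' Compares the combination at `(gamma_G, gamma_A)` with the two inflated
#' monotherapies `((1+theta_G) gamma_G, 0)` and `(0, (1+theta_A) gamma_A)`:
#' \deqn{\sigma = \frac{E(\gamma_G,\gamma_A)}{\max\{E((1+\theta_G)\gamma_G, 0),\; E(0,(1+\theta_A)\gamma_A)\}} - 1.}
#' Positive synergy means the combination beats both single agents at their
#' inflated doses.  The inflation factors encode differential toxicity:
#' the defaults `theta_G = 1`, `theta_A = 0.5` compare against `(2 gamma_G, 0)`
#' and `(0, 1.5 gamma_A)` because anti-PD-1 is the more toxic agent.
#'
#' @param gamma_G,gamma_A combination doses; at least one must be positive.
#' @param theta_G,theta_A monotherapy inflation factors.
#' @param params,settings forwarded to [simulate_tumor()].
#' @param cache optional [new_r60_cache()].
#' @return Synergy (dimensionless).  Errors if both inflated monotherapies
#'   have nonpositive efficacy (undefined synergy).
#' @export
synergy <- function(gamma_G, gamma_A, theta_G = 1, theta_A = 0.5,
                    params = default_parameters(),
                    settings = solver_settings(), cache = new_r60_cache()) {
  if (gamma_G <= 0 && gamma_A <= 0)
    stop("synergy requires gamma_G > 0 or gamma_A > 0")
  eAB <- efficacy(gamma_G, gamma_A, params, settings, cache)
  eG <- efficacy((1 + theta_G) * gamma_G, 0, params, settings, cache)
  eA <- efficacy(0, (1 + theta_A) * gamma_A, params, settings, cache)
  den <- max(eG, eA)
  if (den <= 0)
    stop("undefined synergy: both inflated monotherapies are ineffective")
  eAB / den - 1
}

#' Efficacy or synergy map over a dose grid
#'
#' Fills a grid over `(gamma_G, gamma_A)` with efficacy or synergy values.
#' Synergy needs three simulations per grid point; the inflated
#' monotherapies are shared along rows/columns and computed once
#' (memoized), and for synergy the per-column optimal anti-PD-1 dose curve
#' `gamma_AG(gamma_G)` is extracted by argmax with quadratic refinement.
#'
#' Published grid ranges: efficacy over `[0, 4.8e-10] x [0, 4e-10]`,
#' synergy over `[0, 2.4e-10] x [0, 2e-10]` g/cm^3/day.
#'
#' @param gamma_G,gamma_A ascending dose grids (g/cm^3/day), including 0.
#' @param kind `"efficacy"` or `"synergy"`.
#' @param theta_G,theta_A synergy inflation factors (ignored for efficacy).
#' @param params,settings forwarded to [simulate_tumor()].
#' @param cache optional [new_r60_cache()].
#' @return Object of class `"dose_map"`: dose grids, `value` matrix
#'   (rows = `gamma_G`, columns = `gamma_A`; synergy is `NA` where undefined,
#'   i.e. at the origin), the `r60` matrix, the control radius, and for
#'   synergy the optimal-dose curve in `$curve`.
#' @export
dose_map <- function(gamma_G, gamma_A, kind = c("efficacy", "synergy"),
                     theta_G = 1, theta_A = 0.5,
                     params = default_parameters(),
                     settings = solver_settings(),
                     cache = new_r60_cache()) {
  kind <- match.arg(kind)
  stopifnot(!is.unsorted(gamma_G, strictly = TRUE),
            !is.unsorted(gamma_A, strictly = TRUE),
            all(gamma_G >= 0), all(gamma_A >= 0))
  nG <- length(gamma_G); nA <- length(gamma_A)
  val <- matrix(NA_real_, nG, nA)
  r60 <- matrix(NA_real_, nG, nA)
  ctrl <- .r60(0, 0, params, settings, cache)$R60
  for (i in seq_len(nG)) {
    for (j in seq_len(nA)) {
      r60[i, j] <- .r60(gamma_G[i], gamma_A[j], params, settings, cache)$R60
      if (kind == "efficacy") {
        val[i, j] <- (ctrl - r60[i, j]) / ctrl
      } else {
        if (gamma_G[i] <= 0 && gamma_A[j] <= 0) next
        eAB <- (ctrl - r60[i, j]) / ctrl
        eG <- efficacy((1 + theta_G) * gamma_G[i], 0, params, settings, cache)
        eA <- efficacy(0, (1 + theta_A) * gamma_A[j], params, settings, cache)
        den <- max(eG, eA)
        val[i, j] <- if (den > 0) eAB / den - 1 else NA_real_
      }
    }
  }
  out <- structure(list(gamma_G = gamma_G, gamma_A = gamma_A, value = val,
                        r60 = r60, control_r60 = ctrl, kind = kind,
                        theta_G = theta_G, theta_A = theta_A),
                   class = "dose_map")
  if (kind == "synergy") out$curve <- optimal_dose_curve(out)
  out
}

#' Optimal anti-PD-1 dose curve
#'
#' For each vaccine dose column of a synergy map, the anti-PD-1 dose
#' maximizing synergy: discrete argmax over the grid, refined by a quadratic
#' fit through the three points around an interior maximum.
#'
#' @param map a synergy [dose_map()].
#' @return Data frame with `gamma_G` and the maximizing `gamma_AG`
#'   (`NA` for columns with no defined values).
#' @export
optimal_dose_curve <- function(map) {
  stopifnot(inherits(map, "dose_map"), map$kind == "synergy")
  gA <- map$gamma_A
  gAG <- vapply(seq_along(map$gamma_G), function(i) {
    v <- map$value[i, ]
    if (all(is.na(v))) return(NA_real_)
    k <- which.max(v)
    if (k == 1 || k == length(v) || any(is.na(v[(k - 1):(k + 1)])))
      return(gA[k])
    # vertex of the parabola through the three bracketing points
    x <- gA[(k - 1):(k + 1)]; y <- v[(k - 1):(k + 1)]
    d21 <- (y[2] - y[1]) / (x[2] - x[1])
    d32 <- (y[3] - y[2]) / (x[3] - x[2])
    c2 <- (d32 - d21) / (x[3] - x[1])
    if (c2 >= 0) return(gA[k])
    0.5 * (x[1] + x[2] - d21 / c2)
  }, numeric(1))
  data.frame(gamma_G = map$gamma_G, gamma_AG = gAG)
}

#' Day-60 average cell-density maps
#'
#' Runs the dose grid and records the day-60 volume-averaged cancer density
#' and total T-cell density (`T1 + T8`) per dose pair.  Over the published
#' dose ranges the T-cell average rises roughly 6-fold from zero to maximal
#' dose while the cancer average falls by a factor of about 1.075.
#'
#' @param gamma_G,gamma_A ascending dose grids.
#' @param params,settings,cache as in [dose_map()].
#' @return Object of class `"cell_avg_map"` with matrices `C_avg` and
#'   `T_avg` (rows = `gamma_G`).
#' @export
average_cell_maps <- function(gamma_G, gamma_A,
                              params = default_parameters(),
                              settings = solver_settings(),
                              cache = new_r60_cache()) {
  nG <- length(gamma_G); nA <- length(gamma_A)
  Cm <- matrix(NA_real_, nG, nA)
  Tm <- matrix(NA_real_, nG, nA)
  for (i in seq_len(nG)) {
    for (j in seq_len(nA)) {
      res <- .r60(gamma_G[i], gamma_A[j], params, settings, cache)
      Cm[i, j] <- res$C_avg
      Tm[i, j] <- res$T_avg
    }
  }
  structure(list(gamma_G = gamma_G, gamma_A = gamma_A,
                 C_avg = Cm, T_avg = Tm),
            class = "cell_avg_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("%s map: %d x %d dose grid, gamma_G up to %.3g, gamma_A up to %.3g\n",
              x$kind, length(x$gamma_G), length(x$gamma_A),
              max(x$gamma_G), max(x$gamma_A)))
  cat(sprintf("  values in [%.3g, %.3g]; control R60 = %.4g cm\n",
              min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE),
              x$control_r60))
  invisible(x)
}

#' Plot a dose map
#'
#' Heatmap of the efficacy or synergy values; for a synergy map the optimal
#' dose curve is overlaid.
#'
#' @param x a `"dose_map"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.dose_map <- function(x, ...) {
  image(x$gamma_G, x$gamma_A, x$value, xlab = "gamma_G [g/cm3/day]",
        ylab = "gamma_A [g/cm3/day]", main = paste(x$kind, "map"), ...)
  if (!is.null(x$curve))
    lines(x$curve$gamma_G, x$curve$gamma_AG, lwd = 2)
  invisible(x)
}
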