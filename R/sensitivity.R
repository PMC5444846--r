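#' Sensitivity analysis specification
#'
#' Latin hypercube design over the activation/killing/checkpoint parameters
#' whose uncertainty matters most: `lambda_DC`, `lambda_DG`, `lambda_T1I12`,
#' `lambda_T1I2`, `lambda_T8I12`, `lambda_T8I2`, `Kp_TQ`, `eta1`, `eta8`.
#' Each range spans half to twice the baseline value (uniform within the
#' range).  The outcome is the tumor radius at day 60 under the reference
#' dosing `gamma_G = gamma_A = 1e-10` g/cm^3/day.  The published analysis
#' used 1000 samples.
#'
#' @param n number of Latin hypercube samples (at least 10).
#' @param seed RNG seed making the design reproducible.
#' @param gamma_G,gamma_A dosing context for the outcome simulations.
#' @param parameters character vector of parameter names to vary.
#' @param lower,upper multiplicative range bounds relative to baseline.
#' @param params baseline parameters the ranges are centered on.
#' @return Object of class `"sensitivity_spec"` with a `ranges` matrix
#'   (rows = parameters, columns `lower`/`upper`).
#' @export
sensitivity_spec <- function(n = 1000, seed = 1L,
                             gamma_G = 1e-10, gamma_A = 1e-10,
                             parameters = c("lambda_DC", "lambda_DG",
                                            "lambda_T1I12", "lambda_T1I2",
                                            "lambda_T8I12", "lambda_T8I2",
                                            "Kp_TQ", "eta1", "eta8"),
                             lower = 0.5, upper = 2,
                             params = default_parameters()) {
  stopifnot(n >= 10, lower > 0, upper > lower)
  if (!all(parameters %in% names(params)))
    stop("unknown parameter in 'parameters'")
  base <- unlist(unclass(params)[parameters])
  ranges <- cbind(lower = lower * base, upper = upper * base)
  rownames(ranges) <- parameters
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 gamma_G = gamma_G, gamma_A = gamma_A,
                 parameters = parameters, ranges = ranges, params = params),
            class = "sensitivity_spec")
}

#' Latin hypercube sample of the parameter space
#'
#' Stratified uniform design: for each parameter the `n` draws occupy the
#' `n` equal-probability strata of its range in randomly permuted order
#' (via [lhs::randomLHS()]).  Deterministic given the spec's seed.
#'
#' @param spec a [sensitivity_spec()].
#' @return `n x k` matrix of parameter values, columns named after the
#'   parameters.
#' @export
lhs_sample <- function(spec) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  k <- length(spec$parameters)
  set.seed(spec$seed)
  U <- lhs::randomLHS(spec$n, k)
  lo <- spec$ranges[, "lower"]; hi <- spec$ranges[, "upper"]
  X <- sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(X) <- spec$parameters
  X
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the design matrix and the outcome (midranks for ties),
#' then for each parameter correlates the residuals of its ranks and the
#' outcome ranks after linear adjustment for the other parameters'
#' ranks.  P-values come from the t statistic with `n - 2 - (k - 1)`
#' degrees of freedom.  With a single parameter the PRCC reduces to the
#' Spearman correlation.
#'
#' @param X `n x k` numeric design matrix (no constant columns).
#' @param y numeric outcome of length `n`.
#' @return Data frame with `parameter`, `prcc`, `p_value`; coefficients lie
#'   in \[-1, 1\].
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n > k + 2)
  if (any(apply(X, 2, function(v) diff(range(v))) == 0))
    stop("constant design column")
  Rx <- apply(X, 2, rank)
  ry <- rank(y)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  df <- n - 2 - (k - 1)
  res <- lapply(seq_len(k), function(j) {
    Z <- cbind(1, Rx[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) stop("singular adjustment matrix")
    ex <- qr.resid(qz, Rx[, j])
    ey <- qr.resid(qz, ry)
    r <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(parameter = nm[j], prcc = r,
               p_value = 2 * pt(-abs(tstat), df))
  })
  do.call(rbind, res)
}

#' Latin hypercube / PRCC sensitivity analysis of the day-60 radius
#'
#' Draws the Latin hypercube design, runs one simulation per sample (the
#' varied parameters replace their baseline values; dosing at the spec's
#' reference strengths) and computes PRCCs of R(60) with respect to each
#' parameter.  All of the varied parameters promote the immune response or
#' checkpoint relief, so all coefficients are expected to be negative, with
#' the DC activation rate `lambda_DC` and the checkpoint constant `Kp_TQ`
#' among the most negative.
#'
#' Failed simulations are dropped with a warning when they are fewer than
#' 1% of the samples, otherwise the analysis aborts.
#'
#' @param spec a [sensitivity_spec()].
#' @param settings solver settings for the outcome simulations; sensitivity
#'   runs are usually done on a coarser mesh than single-run studies.
#' @return Object of class `"prcc_result"`: the PRCC table in `$table`
#'   (ordered as in the spec), the design in `$design`, outcomes in `$R60`.
#' @export
run_sensitivity <- function(spec,
                            settings = solver_settings(n_nodes = 40,
                                                       tau = 0.02)) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  X <- lhs_sample(spec)
  dosing <- dosing_schedule(spec$gamma_G, spec$gamma_A)
  y <- rep(NA_real_, spec$n)
  for (i in seq_len(spec$n)) {
    p <- spec$params
    for (nm in spec$parameters) p[[nm]] <- X[i, nm]
    y[i] <- tryCatch({
      sim <- simulate_tumor(p, dosing, settings)
      sim$radius[length(sim$radius)]
    }, error = function(e) NA_real_)
  }
  bad <- is.na(y)
  if (any(bad)) {
    if (mean(bad) >= 0.01)
      stop(sum(bad), " of ", spec$n, " simulations failed")
    warning(sum(bad), " simulations failed and were excluded")
  }
  tab <- prcc(X[!bad, , drop = FALSE], y[!bad])
  structure(list(table = tab, design = X, R60 = y, spec = spec,
                 settings = settings),
            class = "prcc_result")
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("PRCC of R(60) over %d Latin hypercube samples (dosing %.3g / %.3g):\n",
              x$spec$n, x$spec$gamma_G, x$spec$gamma_A))
  tab <- x$table
  tab$prcc <- signif(tab$prcc, 3)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot PRCC results
#'
#' Horizontal bar chart of the coefficients, most negative first.
#'
#' @param x a `"prcc_result"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.prcc_result <- function(x, ...) {
  tab <- x$table[order(x$table$prcc), ]
  barplot(tab$prcc, names.arg = tab$parameter, horiz = TRUE, las = 1,
          xlab = "PRCC of R(60)", ...)
  abline(v = 0)
  invisible(x)
}
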