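#' Moment-matched gamma or beta distribution
#'
#' Method-of-moments parameterisation used by the probabilistic sensitivity
#' analysis: costs are gamma distributed (`shape = mean^2/se^2`,
#' `scale = se^2/mean`), probabilities and utilities beta distributed
#' (`nu = mean(1-mean)/se^2 - 1`, `alpha = mean*nu`, `beta = (1-mean)*nu`).
#' The resulting distribution has exactly the requested mean and standard
#' error.
#'
#' @param family `"gamma"` or `"beta"`.
#' @param mean Target mean (gamma: > 0; beta: in (0,1)).
#' @param se Target standard error (> 0; beta requires
#'   `se^2 < mean*(1-mean)`).
#' @return A list of class `mdt_dist` with the family, moments and shape
#'   parameters.
#' @export
moment_match <- function(family = c("gamma", "beta"), mean, se) {
  family <- match.arg(family)
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  if (family == "gamma") {
    if (mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
    out <- list(family = "gamma", mean = mean, se = se,
                shape = mean^2 / se^2, scale = se^2 / mean)
  } else {
    if (mean <= 0 || mean >= 1)
      stop("beta mean must be in (0,1)", call. = FALSE)
    if (se^2 >= mean * (1 - mean))
      stop("infeasible beta se: se^2 must be < mean*(1-mean)", call. = FALSE)
    nu <- mean * (1 - mean) / se^2 - 1
    out <- list(family = "beta", mean = mean, se = se,
                alpha = mean * nu, beta = (1 - mean) * nu)
  }
  structure(out, class = "mdt_dist")
}

#' Draw from a moment-matched distribution
#'
#' @param dist A `mdt_dist` from [moment_match()].
#' @param n Number of draws.
#' @return Numeric vector of draws.
#' @export
draw_dist <- function(dist, n = 1) {
  if (dist$family == "gamma")
    stats::rgamma(n, shape = dist$shape, scale = dist$scale)
  else
    stats::rbeta(n, dist$alpha, dist$beta)
}

#' Default uncertainty table for a spec
#'
#' Where the primary sources do not report a standard error the default is
#' `se = rel_se * mean` (10\% of the deterministic value), truncated for
#' beta parameters to 95\% of the feasibility bound
#' `sqrt(mean*(1-mean))`.  Parameters with mean 0 or (for beta) mean 1 are
#' excluded: they carry no samplable uncertainty under moment matching.
#'
#' @param spec A `mdt_spec`.
#' @param rel_se Relative standard error applied to every parameter.
#' @return Data frame `parameter`, `type`, `family`, `mean`, `se`.
#' @export
default_uncertainty <- function(spec, rel_se = 0.1) {
  pt <- param_table(spec)
  pt$family <- ifelse(pt$type == "cost", "gamma", "beta")
  keep <- pt$value > 0 & !(pt$family == "beta" & pt$value >= 1)
  pt <- pt[keep, , drop = FALSE]
  pt$mean <- pt$value
  pt$se <- rel_se * pt$mean
  beta <- pt$family == "beta"
  bmax <- sqrt(pt$mean[beta] * (1 - pt$mean[beta]))
  pt$se[beta] <- pmin(pt$se[beta], 0.95 * bmax)
  pt[, c("parameter", "type", "family", "mean", "se")]
}

## uncertainty table: stored on the spec, or the default
uncertainty_table <- function(spec) {
  if (is.null(spec$uncertainty)) default_uncertainty(spec) else spec$uncertainty
}

#' Sample one perturbed parameter set
#'
#' Replaces every parameter listed in the uncertainty table by a single
#' draw from its moment-matched distribution, then enforces the utility
#' ordering by capping each sampled utility at the sampled utility of the
#' preceding (less progressed) state: a more progressed state can never
#' have the higher utility.
#'
#' @param spec A `mdt_spec`.
#' @return A perturbed `mdt_spec` (uses the current RNG state; seed via
#'   [set.seed()] or [run_psa()]).
#' @export
draw_parameter_set <- function(spec) {
  un <- uncertainty_table(spec)
  draws <- numeric(nrow(un))
  for (i in seq_len(nrow(un)))
    draws[i] <- draw_dist(moment_match(un$family[i], un$mean[i], un$se[i]))
  names(draws) <- un$parameter
  ## utility ordering cap, applied on the sampled values
  if (all(c("u_adt_free", "u_adt") %in% names(draws)))
    draws["u_adt"] <- min(draws["u_adt"], draws["u_adt_free"])
  if (all(c("u_adt", "u_crpc") %in% names(draws)))
    draws["u_crpc"] <- min(draws["u_crpc"], draws["u_adt"])
  out <- set_params(spec, draws)
  attr(out, "psa_draws") <- draws
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Runs `n` independent parameter draws, each propagated through the cohort
#' engine for every strategy.  Reproducible: the same seed yields a
#' bit-identical draw set.
#'
#' @param spec A valid `mdt_spec`.
#' @param n Number of iterations (base case 10000).
#' @param seed Integer RNG seed.
#' @return An object of class `mdt_psa`: `params` (`n x p` matrix of sampled
#'   parameters), `cost` and `qaly` (`n x strategies` matrices), `n`,
#'   `seed`, `wtp`.
#' @export
run_psa <- function(spec, n = 10000, seed = 1) {
  stopifnot(n >= 1)
  stop_if_invalid(spec)
  set.seed(seed)
  strategies <- spec$strategies
  cost <- matrix(NA_real_, n, length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost

  ## moment-match every varied parameter once, then draw column-wise
  un <- uncertainty_table(spec)
  dists <- lapply(seq_len(nrow(un)), function(i)
    moment_match(un$family[i], un$mean[i], un$se[i]))
  params <- matrix(NA_real_, n, nrow(un),
                   dimnames = list(NULL, un$parameter))
  for (j in seq_len(nrow(un))) params[, j] <- draw_dist(dists[[j]], n)
  ## utility ordering cap per iteration
  if (all(c("u_adt_free", "u_adt") %in% un$parameter))
    params[, "u_adt"] <- pmin(params[, "u_adt"], params[, "u_adt_free"])
  if (all(c("u_adt", "u_crpc") %in% un$parameter))
    params[, "u_crpc"] <- pmin(params[, "u_crpc"], params[, "u_adt"])

  for (i in seq_len(n)) {
    ds <- set_params(spec, params[i, ])
    out <- run_all_strategies(ds, validate = FALSE)
    cost[i, ] <- vapply(out, `[[`, numeric(1), "discounted_cost")
    qaly[i, ] <- vapply(out, `[[`, numeric(1), "discounted_qaly")
  }
  structure(list(params = params, cost = cost, qaly = qaly,
                 n = n, seed = seed, wtp = spec$wtp),
            class = "mdt_psa")
}

#' @export
print.mdt_psa <- function(x, ...) {
  cat(sprintf("<mdt_psa> %d iterations (seed %d), strategies: %s\n",
              x$n, x$seed, paste(colnames(x$cost), collapse = ", ")))
  for (s in colnames(x$cost))
    cat(sprintf("  %s: mean cost €%.0f, mean QALY %.3f\n",
                s, mean(x$cost[, s]), mean(x$qaly[, s])))
  invisible(x)
}

## per-iteration increments for a pair c(new, comparator)
psa_increments <- function(draws, pair) {
  list(dc = draws$cost[, pair[1L]] - draws$cost[, pair[2L]],
       dq = draws$qaly[, pair[1L]] - draws$qaly[, pair[2L]])
}

#' Cost-effectiveness acceptability curve for a strategy pair
#'
#' At each willingness-to-pay value the curve is the fraction of PSA
#' iterations in which the incremental net monetary benefit of the first
#' strategy over the second is positive.
#'
#' @param draws A `mdt_psa`.
#' @param pair Character vector `c(new, comparator)`.
#' @param wtp_grid Numeric vector of thresholds (euro/QALY).
#' @return An object of class `mdt_ceac`: data frame `wtp`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(draws, pair, wtp_grid = seq(0, 100000, by = 2000)) {
  inc <- psa_increments(draws, pair)
  p <- vapply(wtp_grid,
              function(l) mean(l * inc$dq - inc$dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = p),
            class = c("mdt_ceac", "data.frame"),
            pair = pair)
}

#' Multi-strategy cost-effectiveness acceptability curve
#'
#' At each threshold every strategy's value is the fraction of iterations
#' in which it attains the maximum net monetary benefit; the curves sum to
#' one (ties broken by the fixed strategy order of the draw set).
#'
#' @param draws A `mdt_psa`.
#' @param wtp_grid Numeric vector of thresholds.
#' @return Data frame of class `mdt_ceac`: `wtp` plus one probability
#'   column per strategy.
#' @export
multi_ceac <- function(draws, wtp_grid = seq(0, 100000, by = 2000)) {
  strategies <- colnames(draws$cost)
  out <- matrix(0, length(wtp_grid), length(strategies),
                dimnames = list(NULL, strategies))
  for (j in seq_along(wtp_grid)) {
    nmb <- wtp_grid[j] * draws$qaly - draws$cost
    best <- max.col(nmb, ties.method = "first")
    out[j, ] <- tabulate(best, nbins = length(strategies)) / draws$n
  }
  structure(data.frame(wtp = wtp_grid, out),
            class = c("mdt_ceac", "data.frame"))
}

#' Summarise a PSA draw set for one strategy pair
#'
#' Reports the two standard "mean ICER" estimators side by side — the ratio
#' of mean increments and the mean of per-iteration ICERs restricted to the
#' north-east quadrant — together with quadrant occupancy, the fraction of
#' dominant iterations and the probability of cost-effectiveness at the
#' threshold.
#'
#' @param draws A `mdt_psa`.
#' @param pair Character vector `c(new, comparator)`.
#' @param wtp Threshold (defaults to the spec's, carried on the draw set).
#' @return A list of class `mdt_psa_summary`.
#' @export
psa_summary <- function(draws, pair, wtp = draws$wtp) {
  inc <- psa_increments(draws, pair)
  dc <- inc$dc; dq <- inc$dq
  ne <- dc > 0 & dq > 0
  quadrants <- c(NE = mean(dc > 0 & dq > 0), NW = mean(dc > 0 & dq <= 0),
                 SW = mean(dc <= 0 & dq <= 0), SE = mean(dc <= 0 & dq > 0))
  structure(list(
    pair = pair, n = draws$n, wtp = wtp,
    mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq),
    icer_ratio_of_means = mean(dc) / mean(dq),
    icer_ne_mean = if (any(ne)) mean(dc[ne] / dq[ne]) else NA_real_,
    quadrant_fractions = quadrants,
    prob_cost_effective = mean(wtp * dq - dc > 0),
    frac_dominant = mean(dc < 0 & dq > 0)
  ), class = "mdt_psa_summary")
}

#' @export
print.mdt_psa_summary <- function(x, ...) {
  cat(sprintf("<mdt_psa_summary> %s vs %s (%d iterations)\n",
              x$pair[1L], x$pair[2L], x$n))
  cat(sprintf("  mean Δcost €%.0f, mean ΔQALY %.3f\n",
              x$mean_delta_cost, x$mean_delta_qaly))
  cat(sprintf("  ICER (ratio of means) €%.0f/QALY; NE-quadrant mean €%s/QALY\n",
              x$icer_ratio_of_means,
              if (is.na(x$icer_ne_mean)) "—"
              else sprintf("%.0f", x$icer_ne_mean)))
  cat(sprintf("  P(cost-effective at €%s): %.1f%%; dominant in %.1f%%\n",
              format(x$wtp, big.mark = ","),
              100 * x$prob_cost_effective, 100 * x$frac_dominant))
  invisible(x)
}

#' Cost-effectiveness-plane coordinates of a PSA draw set
#'
#' @param draws A `mdt_psa`.
#' @param pair Character vector `c(new, comparator)`.
#' @return Data frame `delta_cost`, `delta_qaly`, one row per iteration.
#' @export
ce_plane <- function(draws, pair) {
  inc <- psa_increments(draws, pair)
  data.frame(delta_qaly = inc$dq, delta_cost = inc$dc)
}
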