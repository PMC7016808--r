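## deterministic ICER for one pair under a (possibly perturbed) spec
pair_icer <- function(spec, pair, validate = FALSE) {
  out_new <- accumulate_outcomes(run_cohort(spec, pair[1L]), spec)
  out_cmp <- accumulate_outcomes(run_cohort(spec, pair[2L]), spec)
  compute_icer(out_new, out_cmp)
}

#' One-way (tornado) sensitivity analysis
#'
#' Each varied parameter is set to 80\% and 120\% of its deterministic
#' value, all others held at base, and the deterministic ICER of the pair
#' recorded.  Perturbed probabilities and utilities that would exceed their
#' natural bound are clamped to it (with a `clamped` flag in the output)
#' rather than skipped.  Parameters with zero impact are retained but
#' flagged, mirroring a tornado figure that omits them.
#'
#' @param spec A valid `mdt_spec`.
#' @param pair Character vector `c(new, comparator)`; default MDT vs
#'   surveillance.
#' @param low,high Multipliers for the parameter ends (base 0.8 and 1.2).
#' @return Data frame of class `mdt_tornado`, one row per parameter, sorted
#'   by descending ICER range: `parameter`, `base_value`, `icer_low`,
#'   `icer_high`, `range`, `zero_impact`, `clamped`.
#' @export
one_way_tornado <- function(spec, pair = c("MDT", "SURVEILLANCE"),
                            low = 0.8, high = 1.2) {
  stop_if_invalid(spec)
  base_icer <- pair_icer(spec, pair)$icer
  pt <- param_table(spec)
  bounded <- pt$type %in% c("probability", "utility")

  eval_at <- function(nm, value) {
    pair_icer(set_params(spec, stats::setNames(value, nm)), pair)$icer
  }
  rows <- lapply(seq_len(nrow(pt)), function(i) {
    v <- pt$value[i]
    lo <- v * low
    hi <- v * high
    clamped <- FALSE
    if (bounded[i] && hi > 1) { hi <- 1; clamped <- TRUE }
    icer_low <- eval_at(pt$parameter[i], lo)
    icer_high <- eval_at(pt$parameter[i], hi)
    data.frame(parameter = pt$parameter[i], base_value = v,
               icer_low = icer_low, icer_high = icer_high,
               range = abs(icer_high - icer_low),
               zero_impact = isTRUE(all.equal(icer_low, icer_high)) &&
                             isTRUE(all.equal(icer_low, base_icer)),
               clamped = clamped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("mdt_tornado", "data.frame")
  out
}

## set a one-off cost parameter to an absolute value.  "first_month_mdt"
## is the composed first-month total and is overridden as a whole.
set_cost_value <- function(spec, cost_parameter, value) {
  if (cost_parameter == "first_month_mdt") {
    spec$costs$events$first_month_mdt <- value
    spec
  } else if (cost_parameter %in% names(spec$costs$events)) {
    spec$costs$events[[cost_parameter]] <- value
    spec
  } else {
    set_params(spec, stats::setNames(value, cost_parameter))
  }
}

#' Maximum cost at which a strategy remains cost-effective
#'
#' Varies one one-off cost (e.g. the total first-month MDT cost, or the
#' SBRT course alone) and finds, by bisection to 1-euro precision, the
#' largest value at which the pair is still cost-effective at the
#' willingness-to-pay threshold.  Because the discounted total cost — and
#' hence the ICER numerator — is affine in any strategy-specific one-off
#' cost, the bisection is cross-checked against the closed-form root of
#' the affine ICER; both are returned.
#'
#' @param spec A valid `mdt_spec`.
#' @param cost_parameter `"first_month_mdt"`, an event-cost name
#'   (`"sbrt_course"`, ...), or any cost parameter of [param_table()].
#' @param pair Character vector `c(new, comparator)`.
#' @param wtp Threshold (default: the spec's).
#' @return List of class `mdt_threshold`: `threshold` (euro, NA with
#'   `feasible = FALSE` when not cost-effective even at zero cost),
#'   `closed_form`, `cost_parameter`, `pair`, `wtp`.
#' @export
cost_threshold_search <- function(spec, cost_parameter = "first_month_mdt",
                                  pair = c("MDT", "SURVEILLANCE"),
                                  wtp = spec$wtp) {
  stop_if_invalid(spec)
  ce_at <- function(value) {
    is_cost_effective(pair_icer(set_cost_value(spec, cost_parameter, value),
                                pair), wtp)
  }
  icer_at <- function(value)
    pair_icer(set_cost_value(spec, cost_parameter, value), pair)

  ## closed form: delta_cost(c) = a + b*c with constant delta_qaly
  r0 <- icer_at(0)
  r1 <- icer_at(10000)
  b <- (r1$delta_cost - r0$delta_cost) / 10000
  closed_form <- if (b > 0 && r0$delta_qaly > 0)
    (wtp * r0$delta_qaly - r0$delta_cost) / b
  else NA_real_

  if (!ce_at(0))
    return(structure(list(threshold = NA_real_, feasible = FALSE,
                          closed_form = closed_form,
                          cost_parameter = cost_parameter, pair = pair,
                          wtp = wtp), class = "mdt_threshold"))

  ## bracket upwards, then bisect to €1
  hi <- max(2 * first_month_mdt_cost(spec), 1000)
  it <- 0L
  while (ce_at(hi) && it < 60L) { hi <- hi * 2; it <- it + 1L }
  if (ce_at(hi))
    stop("cost parameter never renders the pair cost-ineffective",
         call. = FALSE)
  lo <- 0
  while (hi - lo > 0.5) {
    mid <- (lo + hi) / 2
    if (ce_at(mid)) lo <- mid else hi <- mid
  }
  structure(list(threshold = (lo + hi) / 2, feasible = TRUE,
                 closed_form = closed_form,
                 cost_parameter = cost_parameter, pair = pair, wtp = wtp),
            class = "mdt_threshold")
}

#' @export
print.mdt_threshold <- function(x, ...) {
  cat(sprintf("<mdt_threshold> %s, %s vs %s at WTP €%s: %s\n",
              x$cost_parameter, x$pair[1L], x$pair[2L],
              format(x$wtp, big.mark = ","),
              if (!x$feasible) "no feasible threshold"
              else sprintf("max cost €%.0f (closed form €%.0f)",
                           x$threshold, x$closed_form)))
  invisible(x)
}

#' Scale the clinical effect of MDT between the trial estimate and no effect
#'
#' At scale `s` the MDT arm's ADT-free-to-ADT interval probabilities become
#' `p_surv - s * (p_surv - p_mdt)`: `s = 1` reproduces the trial effect
#' bit-exactly and `s = 0` makes MDT clinically identical to surveillance
#' (the ICER then diverges as the QALY gain vanishes).  The default
#' interpolates on the probability scale; `scale_on = "hazard"`
#' interpolates the per-interval log-hazards instead.
#'
#' @param spec A valid `mdt_spec`.
#' @param scales Numeric vector of effect fractions in `[0, 1]`.
#' @param pair Character vector `c(new, comparator)`.
#' @param scale_on `"probability"` (default) or `"hazard"`.
#' @return Data frame: `scale`, `delta_cost`, `delta_qaly`, `icer`,
#'   `classification`, `cost_effective` (at the spec's WTP).
#' @export
effect_scaling_scan <- function(spec, scales = seq(1, 0, by = -0.1),
                                pair = c("MDT", "SURVEILLANCE"),
                                scale_on = c("probability", "hazard")) {
  scale_on <- match.arg(scale_on)
  stop_if_invalid(spec)
  if (any(scales < 0 | scales > 1))
    stop("scales must be in [0,1]", call. = FALSE)
  tr <- spec$transitions
  mdt_rows <- which(tr$strategy == "MDT" & tr$from == "ADT_FREE" &
                    tr$to == "ADT")
  surv_rows <- tr[tr$strategy == "SURVEILLANCE" & tr$from == "ADT_FREE" &
                  tr$to == "ADT", , drop = FALSE]
  match_surv <- function(start) {
    i <- which(surv_rows$start <= start & surv_rows$end > start)
    surv_rows$prob[i[1L]]
  }
  rows <- lapply(scales, function(s) {
    sp <- spec
    for (i in mdt_rows) {
      p_mdt <- tr$prob[i]
      p_surv <- match_surv(tr$start[i])
      sp$transitions$prob[i] <- if (s == 1) p_mdt
      else if (scale_on == "probability") p_surv - s * (p_surv - p_mdt)
      else {                              # interpolate cumulative hazards
        h <- -log(1 - p_surv) - s * (-log(1 - p_surv) + log(1 - p_mdt))
        1 - exp(-h)
      }
    }
    r <- pair_icer(sp, pair)
    data.frame(scale = s, delta_cost = r$delta_cost,
               delta_qaly = r$delta_qaly, icer = r$icer,
               classification = r$classification,
               cost_effective = is_cost_effective(r, spec$wtp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scenario scan over the magnitude of the standard errors
#'
#' Re-runs the full PSA once per standard-error setting (base scan: 0.05,
#' 0.1, 0.15, 0.2, 0.25), interpreting each value as an absolute standard
#' error for utilities and probabilities and as a relative standard error
#' for costs.  Standard errors infeasible for a beta parameter are held at
#' 95\% of the feasibility bound.
#'
#' @param spec A valid `mdt_spec`.
#' @param se_values Numeric vector of standard-error magnitudes.
#' @param n PSA iterations per setting.
#' @param seed RNG seed (each setting reuses the same seed so settings
#'   differ only through the standard errors).
#' @param pair Character vector `c(new, comparator)`.
#' @return Data frame, one row per setting: `se`, `prob_cost_effective`,
#'   `icer_ratio_of_means`, `frac_dominant`.
#' @export
se_scenario_scan <- function(spec, se_values = c(0.05, 0.1, 0.15, 0.2, 0.25),
                             n = 1000, seed = 1,
                             pair = c("MDT", "SURVEILLANCE")) {
  stop_if_invalid(spec)
  rows <- lapply(se_values, function(se) {
    un <- uncertainty_table(spec)
    gamma <- un$family == "gamma"
    un$se[gamma] <- se * un$mean[gamma]
    bmax <- sqrt(un$mean[!gamma] * (1 - un$mean[!gamma]))
    un$se[!gamma] <- pmin(se, 0.95 * bmax)
    sp <- spec
    sp$uncertainty <- un
    s <- psa_summary(run_psa(sp, n = n, seed = seed), pair)
    data.frame(se = se, prob_cost_effective = s$prob_cost_effective,
               icer_ratio_of_means = s$icer_ratio_of_means,
               frac_dominant = s$frac_dominant)
  })
  do.call(rbind, rows)
}
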