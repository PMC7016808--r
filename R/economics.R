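#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' `ICER = (COST_new - COST_comparator) / (QALY_new - QALY_comparator)` on
#' discounted totals.  The result is classified by cost-effectiveness-plane
#' quadrant: `dominant` (cheaper and more effective), `dominated` (dearer
#' and less effective), `tradeoff_NE` (dearer, more effective),
#' `tradeoff_SW` (cheaper, less effective) or `equal`.  The ICER is
#' undefined when the QALY difference is zero (reported as `NA`, never
#' infinity).
#'
#' @param new,comparator `mdt_outcome` objects from the same spec, or
#'   two-element lists/vectors with `discounted_cost` and `discounted_qaly`.
#' @return An object of class `mdt_icer` with fields `delta_cost`,
#'   `delta_qaly`, `icer` and `classification`.
#' @export
compute_icer <- function(new, comparator) {
  dc <- new$discounted_cost - comparator$discounted_cost
  dq <- new$discounted_qaly - comparator$discounted_qaly
  classification <-
    if (dc == 0 && dq == 0) "equal"
    else if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dq >= 0) "tradeoff_NE"          # includes dq == 0, dc != 0 by cost sign
    else "tradeoff_SW"
  if (dq == 0 && dc != 0)
    classification <- if (dc > 0) "dominated" else "dominant"
  structure(list(
    delta_cost = dc, delta_qaly = dq,
    icer = if (dq != 0) dc / dq else NA_real_,
    classification = classification,
    new = if (!is.null(new$strategy)) new$strategy else NA_character_,
    comparator = if (!is.null(comparator$strategy)) comparator$strategy
                 else NA_character_
  ), class = "mdt_icer")
}

#' @export
print.mdt_icer <- function(x, ...) {
  lbl <- if (!is.na(x$new)) sprintf(" %s vs %s", x$new, x$comparator) else ""
  cat(sprintf("<mdt_icer>%s: Δcost €%.0f, ΔQALY %.3f, ICER %s [%s]\n",
              lbl, x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined"
              else sprintf("€%.0f/QALY", x$icer),
              x$classification))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALY - cost`.  A strategy is cost-effective against a
#' comparator exactly when its incremental NMB is positive, which for a
#' north-east trade-off is equivalent to `ICER < wtp`.
#'
#' @param outcome A `mdt_outcome` (or anything with `discounted_cost` and
#'   `discounted_qaly`).
#' @param wtp Willingness-to-pay threshold, euro per QALY (>= 0).
#' @return NMB in euro.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  if (wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  wtp * outcome$discounted_qaly - outcome$discounted_cost
}

#' Cost-effectiveness verdict at a willingness-to-pay threshold
#'
#' True iff the strategy is dominant, a north-east trade-off with
#' `ICER < wtp`, or a south-west trade-off with `ICER > wtp` (the savings
#' per QALY forgone exceed the threshold); false when dominated.  Consistent
#' with the sign of the incremental net monetary benefit in every quadrant.
#'
#' @param result A `mdt_icer`.
#' @param wtp Threshold, euro/QALY.
#' @return Logical.
#' @export
is_cost_effective <- function(result, wtp) {
  switch(result$classification,
    dominant = TRUE,
    dominated = FALSE,
    equal = FALSE,
    tradeoff_NE = !is.na(result$icer) && result$icer < wtp,
    tradeoff_SW = !is.na(result$icer) && result$icer > wtp,
    stop("unknown classification: ", result$classification, call. = FALSE))
}

#' All pairwise incremental comparisons for a set of outcomes
#'
#' @param outcomes Named list of `mdt_outcome` (as from
#'   [run_all_strategies()]).
#' @param wtp Threshold used for the NMB column.
#' @return Data frame: one row per ordered strategy pair with the deltas,
#'   ICER (NA when undefined), classification and incremental NMB.
#' @export
icer_table <- function(outcomes, wtp = 40000) {
  nms <- names(outcomes)
  rows <- list()
  for (a in nms) for (b in nms) {
    if (a == b) next
    r <- compute_icer(outcomes[[a]], outcomes[[b]])
    rows[[length(rows) + 1L]] <- data.frame(
      new = a, comparator = b,
      delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
      icer = r$icer, classification = r$classification,
      inmb = net_monetary_benefit(outcomes[[a]], wtp) -
             net_monetary_benefit(outcomes[[b]], wtp),
      cost_effective = is_cost_effective(r, wtp),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
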