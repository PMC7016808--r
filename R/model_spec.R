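#' Construct a model specification
#'
#' A `mdt_spec` is the complete declarative description of the decision
#' model: strategies, transition schedule, life table, costs, utilities,
#' toxicity profile, discounting, horizon and the uncertainty (standard
#' error) table driving probabilistic sensitivity analysis.
#'
#' @param transitions Data frame with columns `strategy` (a strategy label or
#'   `"ALL"` for edges shared by every strategy), `from`, `to`, `start`,
#'   `end` (months, the rows for one edge must partition `[0, horizon)`) and
#'   `prob`, the probability that the transition occurs over the interval.
#' @param lifetable Data frame with columns `age` (integer years, contiguous),
#'   `qx` (annual all-cause death probability for males) and `pca_fraction`
#'   (fraction of male deaths at that age attributable to prostate cancer,
#'   removed so the life table only carries non-prostate-cancer mortality).
#' @param utilities Named list with utility weights `adt_free`, `adt`,
#'   `crpc` (death is 0), and optionally `adt_free_split = list(sbrt=,
#'   surgery=)` mixed by `sbrt_fraction`.
#' @param costs Named list; see [make_paramset()] for the full shape:
#'   `state_monthly` (data frame `strategy`, `state`, `cost` in euro/month),
#'   `adt_drug_monthly`, and `events` (named list of one-off euro costs:
#'   `mdt_workup`, `sbrt_course`, `surgery_course`, `repeat_mdt`,
#'   `adt_initiation`).
#' @param toxicities Data frame with columns `name`, `grade`, `prob`,
#'   `cost`, `rate` (intervention rate in clinical practice) and `context`
#'   (`"MDT"`: expected cost per MDT treatment episode; `"ADT"`: expected
#'   monthly management cost while on ADT, applied in the ADT and CRPC
#'   states).
#' @param discount Named list `costs`, `effects`: annual rates (base case
#'   0.03 and 0.015).
#' @param sbrt_fraction Fraction of MDT episodes delivered by stereotactic
#'   body radiotherapy rather than surgery (trial usage ratio, 25/31).
#' @param repeat_mdt_monthly_prob Monthly probability of an additional MDT
#'   round while ADT-free under the MDT strategy.
#' @param horizon_months,cycle_months,start_age,wtp Scalars; defaults are the
#'   base case (60 cycles of 1 month from age 68, willingness to pay
#'   40000 euro/QALY).
#' @param uncertainty Optional data frame (`parameter`, `family`, `mean`,
#'   `se`); when `NULL`, [default_uncertainty()] is applied lazily by the
#'   PSA functions.
#' @param strategies Character vector of strategies to model.
#' @param placeholders Optional data frame (`parameter`, `note`) flagging
#'   values that are placeholders awaiting transcription from their primary
#'   source; the loader and report functions warn when any are present.
#'
#' @return An object of class `mdt_spec` (a named list).
#' @seealso [validate_spec()], [make_paramset()], [load_model_spec()]
#' @export
model_spec <- function(transitions, lifetable, utilities, costs, toxicities,
                       discount = list(costs = 0.03, effects = 0.015),
                       sbrt_fraction = 25 / 31,
                       repeat_mdt_monthly_prob = 0,
                       horizon_months = 60, cycle_months = 1,
                       start_age = 68, wtp = 40000,
                       uncertainty = NULL,
                       strategies = model_strategies(),
                       placeholders = NULL) {
  spec <- structure(list(
    strategies = strategies,
    states = model_states(),
    transitions = as.data.frame(transitions),
    lifetable = as.data.frame(lifetable),
    utilities = utilities,
    costs = costs,
    toxicities = as.data.frame(toxicities),
    discount = discount,
    sbrt_fraction = sbrt_fraction,
    repeat_mdt_monthly_prob = repeat_mdt_monthly_prob,
    horizon_months = horizon_months,
    cycle_months = cycle_months,
    start_age = start_age,
    wtp = wtp,
    uncertainty = uncertainty,
    placeholders = placeholders
  ), class = "mdt_spec")
  spec
}

#' @export
print.mdt_spec <- function(x, ...) {
  cat("<mdt_spec> Markov cost-utility model specification\n")
  cat("  strategies:", paste(x$strategies, collapse = ", "), "\n")
  cat(sprintf("  horizon: %d months (%g-month cycles), start age %g\n",
              x$horizon_months, x$cycle_months, x$start_age))
  cat(sprintf("  discounting: costs %.1f%%/y, effects %.2f%%/y; WTP €%s/QALY\n",
              100 * x$discount$costs, 100 * x$discount$effects,
              format(x$wtp, big.mark = ",")))
  u <- x$utilities
  cat(sprintf("  utilities: ADT-free %.3g, ADT %.3g, CRPC %.3g\n",
              utility_adt_free(x), u$adt, u$crpc))
  if (!is.null(x$placeholders) && nrow(x$placeholders) > 0L)
    cat(sprintf("  %d placeholder value(s) flagged (see $placeholders)\n",
                nrow(x$placeholders)))
  invisible(x)
}

#' Effective ADT-free utility (mixing the SBRT/surgery split when present)
#'
#' @param spec A `mdt_spec`.
#' @return A utility weight in `[0, 1]`.
#' @export
utility_adt_free <- function(spec) {
  u <- spec$utilities
  if (!is.null(u$adt_free_split)) {
    s <- u$adt_free_split
    spec$sbrt_fraction * s$sbrt + (1 - spec$sbrt_fraction) * s$surgery
  } else {
    u$adt_free
  }
}

## one diagnostic row
diag_row <- function(field, rule, value) {
  data.frame(field = field, rule = rule,
             value = paste(format(value), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Validate a model specification
#'
#' Checks every structural invariant of the model and returns diagnostics
#' rather than throwing: an empty data frame means the spec is valid.  Rules
#' cover state/strategy vocabularies, probability and utility ranges, the
#' utility ordering (a more progressed state never has a higher utility),
#' non-negative costs and discount rates, the interval partition of the
#' transition schedule, life-table coverage of the modelled age span, and
#' beta-feasibility of every standard error in the uncertainty table.
#'
#' @param spec A `mdt_spec`.
#' @return A data frame with columns `field`, `rule`, `value`; zero rows iff
#'   the spec is valid.
#' @export
validate_spec <- function(spec) {
  d <- list()
  add <- function(x) d[[length(d) + 1L]] <<- x

  if (!identical(sort(spec$states), sort(MDT_STATES)))
    add(diag_row("states", "exactly ADT_FREE/ADT/CRPC/DEATH", spec$states))
  if (length(spec$strategies) == 0L ||
      !all(spec$strategies %in% MDT_STRATEGIES))
    add(diag_row("strategies", "subset of known strategies", spec$strategies))

  if (spec$horizon_months %% spec$cycle_months != 0)
    add(diag_row("horizon_months", "divisible by cycle_months",
                 spec$horizon_months))
  for (nm in c("costs", "effects"))
    if (spec$discount[[nm]] < 0)
      add(diag_row(paste0("discount$", nm), ">= 0", spec$discount[[nm]]))
  if (spec$wtp < 0) add(diag_row("wtp", ">= 0", spec$wtp))
  if (spec$sbrt_fraction < 0 || spec$sbrt_fraction > 1)
    add(diag_row("sbrt_fraction", "in [0,1]", spec$sbrt_fraction))
  if (spec$repeat_mdt_monthly_prob < 0 || spec$repeat_mdt_monthly_prob > 1)
    add(diag_row("repeat_mdt_monthly_prob", "in [0,1]",
                 spec$repeat_mdt_monthly_prob))

  ## utilities
  u_af <- utility_adt_free(spec)
  u <- c(adt_free = u_af, adt = spec$utilities$adt, crpc = spec$utilities$crpc)
  for (nm in names(u))
    if (is.na(u[[nm]]) || u[[nm]] < 0 || u[[nm]] > 1)
      add(diag_row(paste0("utilities$", nm), "in [0,1]", u[[nm]]))
  if (!(u[["adt_free"]] >= u[["adt"]] && u[["adt"]] >= u[["crpc"]]))
    add(diag_row("utilities", "ordering adt_free >= adt >= crpc", u))

  ## transitions
  tr <- spec$transitions
  if (any(tr$prob < 0 | tr$prob > 1))
    add(diag_row("transitions$prob", "in [0,1]", range(tr$prob)))
  if (any(tr$from == "DEATH"))
    add(diag_row("transitions$from", "no transition out of DEATH", "DEATH"))
  if (!all(tr$from %in% MDT_STATES) || !all(tr$to %in% MDT_STATES))
    add(diag_row("transitions", "states in vocabulary",
                 unique(c(tr$from, tr$to))))
  edges <- unique(tr[, c("strategy", "from", "to")])
  for (i in seq_len(nrow(edges))) {
    rows <- tr[tr$strategy == edges$strategy[i] & tr$from == edges$from[i] &
               tr$to == edges$to[i], , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    ok <- rows$start[1L] == 0 &&
      rows$end[nrow(rows)] == spec$horizon_months &&
      all(rows$end > rows$start) &&
      (nrow(rows) == 1L || all(rows$start[-1L] == rows$end[-nrow(rows)]))
    if (!ok)
      add(diag_row("transitions",
                   sprintf("intervals for %s %s->%s partition [0,%d)",
                           edges$strategy[i], edges$from[i], edges$to[i],
                           spec$horizon_months),
                   paste0(rows$start, "-", rows$end)))
  }

  ## life table
  lt <- spec$lifetable
  if (any(lt$qx < 0 | lt$qx > 1))
    add(diag_row("lifetable$qx", "in [0,1]", range(lt$qx)))
  if (any(lt$pca_fraction < 0 | lt$pca_fraction > 1))
    add(diag_row("lifetable$pca_fraction", "in [0,1]",
                 range(lt$pca_fraction)))
  if (nrow(lt) > 1L && !all(diff(lt$age) == 1L))
    add(diag_row("lifetable$age", "contiguous integer ages", lt$age))
  need <- c(floor(spec$start_age),
            floor(spec$start_age + spec$horizon_months / 12))
  if (min(lt$age) > need[1L] || max(lt$age) < need[2L])
    add(diag_row("lifetable$age",
                 sprintf("covers ages %d..%d", need[1L], need[2L]),
                 range(lt$age)))

  ## costs
  cs <- spec$costs
  if (any(cs$state_monthly$cost < 0))
    add(diag_row("costs$state_monthly", ">= 0", min(cs$state_monthly$cost)))
  for (nm in names(cs$events))
    if (cs$events[[nm]] < 0)
      add(diag_row(paste0("costs$events$", nm), ">= 0", cs$events[[nm]]))
  if (cs$adt_drug_monthly < 0)
    add(diag_row("costs$adt_drug_monthly", ">= 0", cs$adt_drug_monthly))
  if (cs$adt_drug_monthly < 63.4 || cs$adt_drug_monthly > 141.5)
    add(diag_row("costs$adt_drug_monthly",
                 "within Belgian ADT drug price range 63.4-141.5",
                 cs$adt_drug_monthly))

  ## toxicities
  tox <- spec$toxicities
  if (nrow(tox) > 0L) {
    if (any(tox$prob < 0 | tox$prob > 1))
      add(diag_row("toxicities$prob", "in [0,1]", range(tox$prob)))
    if (any(tox$rate < 0 | tox$rate > 1))
      add(diag_row("toxicities$rate", "in [0,1]", range(tox$rate)))
    if (any(tox$cost < 0))
      add(diag_row("toxicities$cost", ">= 0", min(tox$cost)))
    if (any(tox$grade < 2))
      add(diag_row("toxicities$grade",
                   "grade >= 2 (lower grades carry no cost)", min(tox$grade)))
    if (!all(tox$context %in% c("MDT", "ADT")))
      add(diag_row("toxicities$context", "MDT or ADT", unique(tox$context)))
  }

  ## uncertainty table (if materialised)
  un <- spec$uncertainty
  if (!is.null(un) && nrow(un) > 0L) {
    if (any(un$se <= 0))
      add(diag_row("uncertainty$se", "> 0", min(un$se)))
    b <- un[un$family == "beta", , drop = FALSE]
    bad <- b$se^2 >= b$mean * (1 - b$mean)
    if (any(bad))
      add(diag_row("uncertainty", "beta feasibility se^2 < mean*(1-mean)",
                   b$parameter[bad]))
    if (!all(un$family %in% c("gamma", "beta")))
      add(diag_row("uncertainty$family", "gamma or beta", unique(un$family)))
  }

  if (length(d) == 0L) {
    data.frame(field = character(), rule = character(), value = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, d)
  }
}

stop_if_invalid <- function(spec) {
  d <- validate_spec(spec)
  if (nrow(d) > 0L)
    stop("invalid model spec: ", paste(d$field, d$rule, sep = ": ",
                                       collapse = "; "), call. = FALSE)
  invisible(spec)
}

## ---------------------------------------------------------------------------
## Flat parameter map: the surface varied by PSA and tornado analysis.
## Every parameter has a semantic type deciding its PSA family
## (cost -> gamma, probability/utility -> beta).

#' Flat parameter table of a model specification
#'
#' Enumerates every scalar input varied by the sensitivity analyses: the
#' three state utilities, each transition-schedule interval probability, the
#' repeat-MDT monthly probability, toxicity probabilities and costs, state
#' monthly costs, the ADT drug cost and each one-off event cost.  Life-table
#' entries, discount rates, the WTP threshold and the SBRT usage fraction
#' are structural and not part of this surface.
#'
#' @param spec A `mdt_spec`.
#' @return Data frame with columns `parameter`, `type` (`cost`,
#'   `probability`, `utility`) and `value`.
#' @export
param_table <- function(spec) {
  rows <- list()
  add <- function(parameter, type, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, type = type, value = value,
      stringsAsFactors = FALSE)

  add("u_adt_free", "utility", utility_adt_free(spec))
  add("u_adt", "utility", spec$utilities$adt)
  add("u_crpc", "utility", spec$utilities$crpc)

  tr <- spec$transitions
  for (i in seq_len(nrow(tr)))
    add(sprintf("tp_%s_%s_%s_m%02d", tolower(tr$strategy[i]),
                tolower(tr$from[i]), tolower(tr$to[i]), tr$start[i]),
        "probability", tr$prob[i])

  add("p_repeat_mdt", "probability", spec$repeat_mdt_monthly_prob)

  tox <- spec$toxicities
  for (i in seq_len(nrow(tox))) {
    add(paste0("p_tox_", tox$name[i]), "probability", tox$prob[i])
    add(paste0("c_tox_", tox$name[i]), "cost", tox$cost[i])
  }

  sm <- spec$costs$state_monthly
  for (i in seq_len(nrow(sm)))
    add(sprintf("c_state_%s_%s", tolower(sm$strategy[i]),
                tolower(sm$state[i])), "cost", sm$cost[i])
  add("c_adt_drug", "cost", spec$costs$adt_drug_monthly)
  for (nm in names(spec$costs$events))
    add(paste0("c_event_", nm), "cost", spec$costs$events[[nm]])

  do.call(rbind, rows)
}

#' Write a named vector of parameter values back into a spec
#'
#' Inverse of [param_table()]: `values` is a named numeric vector whose
#' names are (a subset of) the `parameter` column.  Utilities written
#' through `u_adt_free` clear any SBRT/surgery split.
#'
#' @param spec A `mdt_spec`.
#' @param values Named numeric vector.
#' @return The modified `mdt_spec`.
#' @export
set_params <- function(spec, values) {
  tr <- spec$transitions
  tr_key <- sprintf("tp_%s_%s_%s_m%02d", tolower(tr$strategy),
                    tolower(tr$from), tolower(tr$to), tr$start)
  sm <- spec$costs$state_monthly
  sm_key <- sprintf("c_state_%s_%s", tolower(sm$strategy), tolower(sm$state))

  for (nm in names(values)) {
    v <- unname(values[[nm]])
    if (nm == "u_adt_free") {
      spec$utilities$adt_free_split <- NULL
      spec$utilities$adt_free <- v
    } else if (nm == "u_adt") {
      spec$utilities$adt <- v
    } else if (nm == "u_crpc") {
      spec$utilities$crpc <- v
    } else if (nm == "p_repeat_mdt") {
      spec$repeat_mdt_monthly_prob <- v
    } else if (nm == "c_adt_drug") {
      spec$costs$adt_drug_monthly <- v
    } else if (startsWith(nm, "c_event_")) {
      ev <- sub("^c_event_", "", nm)
      if (!ev %in% names(spec$costs$events))
        stop("unknown event cost parameter: ", nm, call. = FALSE)
      spec$costs$events[[ev]] <- v
    } else if (startsWith(nm, "p_tox_") || startsWith(nm, "c_tox_")) {
      tox_nm <- sub("^[pc]_tox_", "", nm)
      i <- match(tox_nm, spec$toxicities$name)
      if (is.na(i)) stop("unknown toxicity parameter: ", nm, call. = FALSE)
      col <- if (startsWith(nm, "p_")) "prob" else "cost"
      spec$toxicities[[col]][i] <- v
    } else if (nm %in% tr_key) {
      tr$prob[match(nm, tr_key)] <- v
    } else if (nm %in% sm_key) {
      sm$cost[match(nm, sm_key)] <- v
    } else {
      stop("unknown parameter: ", nm, call. = FALSE)
    }
  }
  spec$transitions <- tr
  spec$costs$state_monthly <- sm
  spec
}
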