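#' Run the cohort simulation for one strategy
#'
#' Propagates the full cohort through the four-state Markov chain:
#' `membership[t+1] = membership[t] %*% P(t)` for `t = 0..n-1`, starting
#' from the strategy's entry state (`ADT_FREE` for MDT and surveillance,
#' `ADT` for immediate ADT).  The trace has `n_cycles + 1` rows.
#'
#' @param spec A valid `mdt_spec`.
#' @param strategy Strategy label.
#' @return An object of class `mdt_trace`: a list with `membership`
#'   (`(n+1) x 4` matrix of cohort fractions), `strategy` and `spec_digest`
#'   bookkeeping fields.
#' @export
run_cohort <- function(spec, strategy) {
  strategy <- match.arg(strategy, MDT_STRATEGIES)
  n <- n_cycles(spec)
  dyn <- strategy_dynamics(spec, strategy)

  m <- matrix(0, n + 1L, 4L, dimnames = list(NULL, MDT_STATES))
  m[1L, entry_state(strategy)] <- 1

  for (t in seq_len(n)) {
    af <- m[t, 1L]; adt <- m[t, 2L]; crpc <- m[t, 3L]; dead <- m[t, 4L]
    p_bg <- dyn$p_bg[t]
    f_af_adt <- af * dyn$p_af_adt[t]
    f_adt_crpc <- adt * dyn$p_adt_crpc[t]
    d_new <- af * p_bg + adt * p_bg + crpc * dyn$p_crpc_death[t]
    m[t + 1L, 1L] <- af - f_af_adt - af * p_bg
    m[t + 1L, 2L] <- adt + f_af_adt - f_adt_crpc - adt * p_bg
    m[t + 1L, 3L] <- crpc + f_adt_crpc - crpc * dyn$p_crpc_death[t]
    m[t + 1L, 4L] <- dead + d_new
  }
  structure(list(membership = m, strategy = strategy, n_cycles = n),
            class = "mdt_trace")
}

#' @export
print.mdt_trace <- function(x, ...) {
  n <- x$n_cycles
  cat(sprintf("<mdt_trace> %s, %d cycles\n", x$strategy, n))
  cat(sprintf("  final occupancy: %s\n",
              paste(sprintf("%s %.3f", MDT_STATES, x$membership[n + 1L, ]),
                    collapse = ", ")))
  invisible(x)
}

## expected one-off toxicity cost per MDT treatment episode and expected
## monthly ADT-toxicity management cost (applied in ADT and CRPC states)
toxicity_costs <- function(spec) {
  tox <- spec$toxicities
  per_context <- function(ctx) {
    rows <- tox[tox$context == ctx, , drop = FALSE]
    if (nrow(rows) == 0L) 0 else sum(rows$prob * rows$rate * rows$cost)
  }
  list(mdt_episode = per_context("MDT"), adt_monthly = per_context("ADT"))
}

#' Total cost of the first MDT month
#'
#' Diagnostic work-up plus the SBRT/surgery course mixed by the trial usage
#' ratio, unless an explicit override (`costs$events$first_month_mdt`) is
#' present — the override is what the cost-threshold scenario varies.
#'
#' @param spec A `mdt_spec`.
#' @return One-off cost in euro.
#' @export
first_month_mdt_cost <- function(spec) {
  ev <- spec$costs$events
  if (!is.null(ev$first_month_mdt)) return(ev$first_month_mdt)
  ev$mdt_workup + spec$sbrt_fraction * ev$sbrt_course +
    (1 - spec$sbrt_fraction) * ev$surgery_course
}

#' Accumulate discounted costs and QALYs from a cohort trace
#'
#' Applies the half-cycle correction as trapezoidal state membership (the
#' mean of cycle-start and cycle-end occupancy), with discount factors
#' evaluated at cycle midpoints, `(1 + r)^-((t + 0.5)/12)`.  State rewards
#' are the per-state monthly cost and the per-state utility divided by 12.
#' One-off event costs (first-month MDT including expected episode
#' toxicity, ADT initiation, repeat-MDT rounds) attach to the transition
#' flows of their cycle and are discounted at that cycle's midpoint,
#' undiluted by the trapezoidal averaging.
#'
#' @param trace A `mdt_trace` from [run_cohort()].
#' @param spec The same `mdt_spec` the trace was generated from.
#' @return An object of class `mdt_outcome`: discounted and undiscounted
#'   totals plus per-cycle cost and QALY streams.
#' @export
accumulate_outcomes <- function(trace, spec) {
  if (!inherits(trace, "mdt_trace"))
    stop("trace must be a mdt_trace", call. = FALSE)
  n <- n_cycles(spec)
  if (trace$n_cycles != n)
    stop("trace and spec disagree on the number of cycles", call. = FALSE)
  strategy <- trace$strategy
  m <- trace$membership
  dyn <- strategy_dynamics(spec, strategy)
  tox <- toxicity_costs(spec)

  ## per-state monthly costs for this strategy
  sm <- spec$costs$state_monthly
  state_cost <- numeric(4L)
  for (s in c("ADT_FREE", "ADT", "CRPC")) {
    row <- sm[(sm$strategy == strategy | sm$strategy == "ALL") &
              sm$state == s, , drop = FALSE]
    state_cost[match(s, MDT_STATES)] <- if (nrow(row)) sum(row$cost) else 0
  }
  state_cost[2L] <- state_cost[2L] + spec$costs$adt_drug_monthly +
    tox$adt_monthly
  state_cost[3L] <- state_cost[3L] + tox$adt_monthly

  u <- c(utility_adt_free(spec), spec$utilities$adt, spec$utilities$crpc, 0)

  ts <- seq_len(n)                      # cycle t = ts - 1
  trap <- (m[ts, , drop = FALSE] + m[ts + 1L, , drop = FALSE]) / 2
  mid_years <- ((ts - 1) + 0.5) * spec$cycle_months / 12
  df_cost <- (1 + spec$discount$costs)^(-mid_years)
  df_eff <- (1 + spec$discount$effects)^(-mid_years)

  qaly_cycle <- as.vector(trap %*% u) * spec$cycle_months / 12
  cost_cycle <- as.vector(trap %*% state_cost)

  ## one-off event costs, flow-attached
  ev <- spec$costs$events
  event_cycle <- numeric(n)
  ## ADT initiation on the flow into the ADT state
  flow_af_adt <- m[ts, 1L] * dyn$p_af_adt
  event_cycle <- event_cycle + flow_af_adt * ev$adt_initiation
  if (strategy == "IMMEDIATE_ADT")
    event_cycle[1L] <- event_cycle[1L] + ev$adt_initiation
  if (strategy == "MDT") {
    episode <- tox$mdt_episode
    event_cycle[1L] <- event_cycle[1L] + first_month_mdt_cost(spec) + episode
    ## repeat rounds: constant monthly probability while ADT-free, from cycle 1
    if (n > 1L) {
      rep_t <- 2:n
      event_cycle[rep_t] <- event_cycle[rep_t] +
        m[rep_t, 1L] * spec$repeat_mdt_monthly_prob *
          (ev$repeat_mdt + episode)
    }
  }
  cost_cycle <- cost_cycle + event_cycle

  structure(list(
    strategy = strategy,
    discounted_cost = sum(cost_cycle * df_cost),
    discounted_qaly = sum(qaly_cycle * df_eff),
    undiscounted_cost = sum(cost_cycle),
    undiscounted_qaly = sum(qaly_cycle),
    cost_cycle = cost_cycle, qaly_cycle = qaly_cycle,
    df_cost = df_cost, df_eff = df_eff
  ), class = "mdt_outcome")
}

#' @export
print.mdt_outcome <- function(x, ...) {
  cat(sprintf("<mdt_outcome> %s: discounted cost €%.0f, %.3f QALYs",
              x$strategy, x$discounted_cost, x$discounted_qaly),
      sprintf("(undiscounted €%.0f, %.3f)\n",
              x$undiscounted_cost, x$undiscounted_qaly))
  invisible(x)
}

#' Deterministic outcomes for every strategy
#'
#' @param spec A valid `mdt_spec`.
#' @param validate Run [validate_spec()] first (disable inside tight PSA
#'   loops where the draw construction already guarantees validity).
#' @return Named list of `mdt_outcome`, one per strategy in the spec.
#' @export
run_all_strategies <- function(spec, validate = TRUE) {
  if (validate) stop_if_invalid(spec)
  out <- lapply(spec$strategies, function(s)
    accumulate_outcomes(run_cohort(spec, s), spec))
  names(out) <- spec$strategies
  out
}

#' Export a cohort trace with its reward streams to a data frame
#'
#' @param trace A `mdt_trace`.
#' @param spec The generating `mdt_spec`.
#' @return Data frame with one row per cycle boundary: state fractions,
#'   per-cycle cost and QALY, and cumulative discounted totals.
#' @export
trace_table <- function(trace, spec) {
  out <- accumulate_outcomes(trace, spec)
  n <- trace$n_cycles
  data.frame(
    cycle = 0:n,
    trace$membership,
    cycle_cost = c(out$cost_cycle, NA),
    cycle_qaly = c(out$qaly_cycle, NA),
    cum_disc_cost = c(cumsum(out$cost_cycle * out$df_cost), NA),
    cum_disc_qaly = c(cumsum(out$qaly_cycle * out$df_eff), NA)
  )
}
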