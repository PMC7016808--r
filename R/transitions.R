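#' Per-cycle event probability from a median time-to-event
#'
#' Constant-hazard (geometric) conversion: the per-cycle probability `p`
#' solves `(1 - p)^(median/cycle) = 0.5`, so cumulative survival at the
#' median is exactly one half.  Used to turn the trial's median ADT-free
#' survival times (21 months after MDT, 13 months under surveillance) into
#' monthly transition probabilities.
#'
#' @param median_months Median time to event, months (> 0).
#' @param cycle_months Cycle length, months (> 0).
#' @return Per-cycle event probability.
#' @examples
#' prob_from_median(21, 1)  # ~0.0325/month
#' @export
prob_from_median <- function(median_months, cycle_months = 1) {
  if (!is.numeric(median_months) || any(median_months <= 0))
    stop("median_months must be > 0", call. = FALSE)
  if (cycle_months <= 0) stop("cycle_months must be > 0", call. = FALSE)
  1 - 0.5^(cycle_months / median_months)
}

#' Convert an interval probability to a per-cycle probability
#'
#' Under a constant hazard within the interval,
#' `p_cycle = 1 - (1 - p_interval)^(cycle/interval)`; compounding the cycle
#' probability back over the interval recovers the interval probability.
#'
#' @param interval_prob Probability of the event over the whole interval.
#' @param interval_months Interval length in months.
#' @param cycle_months Cycle length in months (must divide the interval).
#' @return Per-cycle probability.
#' @export
interval_to_cycle_prob <- function(interval_prob, interval_months,
                                   cycle_months = 1) {
  if (any(interval_prob < 0 | interval_prob > 1))
    stop("interval_prob must be in [0,1]", call. = FALSE)
  if (interval_months <= 0 || cycle_months <= 0)
    stop("interval and cycle lengths must be positive", call. = FALSE)
  if (interval_months %% cycle_months != 0)
    stop("cycle_months must divide interval_months", call. = FALSE)
  1 - (1 - interval_prob)^(cycle_months / interval_months)
}

#' Per-cycle discount rate from an annual rate
#'
#' Compound conversion: `(1 + r)^(cycle/12) - 1`, so twelve monthly factors
#' reproduce one annual factor exactly.
#'
#' @param annual_rate Annual discount rate (>= 0), e.g. 0.03.
#' @param cycle_months Cycle length in months.
#' @return Per-cycle rate.
#' @export
annual_to_cycle_discount <- function(annual_rate, cycle_months = 1) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(cycle_months / 12) - 1
}

#' Background (non-prostate-cancer) mortality for one cycle
#'
#' Looks up the annual all-cause death probability `qx` for the integer age
#' band, removes the prostate-cancer fraction of male deaths
#' (`qx_adj = qx * (1 - pca_fraction)`) because prostate-cancer death is
#' modelled separately in the CRPC state, and converts the adjusted annual
#' probability to the cycle length under a constant hazard.
#'
#' @param lifetable Data frame `age`, `qx`, `pca_fraction`.
#' @param age_years Current (possibly fractional) cohort age.
#' @param cycle_months Cycle length in months.
#' @return Per-cycle background death probability.
#' @export
background_mortality_cycle_prob <- function(lifetable, age_years,
                                            cycle_months = 1) {
  band <- floor(age_years)
  i <- match(band, lifetable$age)
  if (any(is.na(i)))
    stop("age ", paste(band[is.na(i)], collapse = ", "),
         " outside life table range ", min(lifetable$age), "-",
         max(lifetable$age), call. = FALSE)
  qx_adj <- lifetable$qx[i] * (1 - lifetable$pca_fraction[i])
  interval_to_cycle_prob(qx_adj, 12, cycle_months)
}

## ---------------------------------------------------------------------------
## Per-strategy cycle-by-cycle hazard vectors (the engine's fast path).

## monthly probability vector over cycles 0..(n-1) for one edge; zero where
## the edge does not exist for this strategy
edge_monthly_probs <- function(spec, strategy, from, to) {
  n <- n_cycles(spec)
  p <- numeric(n)
  tr <- spec$transitions
  rows <- tr[(tr$strategy == strategy | tr$strategy == "ALL") &
             tr$from == from & tr$to == to, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    idx <- seq(rows$start[i] / spec$cycle_months + 1L,
               rows$end[i] / spec$cycle_months)
    p[idx] <- interval_to_cycle_prob(rows$prob[i],
                                     rows$end[i] - rows$start[i],
                                     spec$cycle_months)
  }
  p
}

n_cycles <- function(spec) as.integer(spec$horizon_months / spec$cycle_months)

#' Per-cycle transition dynamics of one strategy
#'
#' Internal workhorse shared by [run_cohort()], [accumulate_outcomes()] and
#' [build_transition_matrix()].  Disease transitions are applied to the
#' survivors of that cycle's death risk (off-diagonal disease entries scaled
#' by `1 - p_death`), which guarantees row-stochasticity; prostate-cancer
#' specific death is combined with background death in the CRPC state as
#' independent competing risks.
#'
#' @return A list of length-`n_cycles` vectors: `p_bg` background death,
#'   `p_crpc_death` total death probability from CRPC, and the *survivor
#'   scaled* progression probabilities `p_af_adt`, `p_adt_crpc`.
#' @noRd
strategy_dynamics <- function(spec, strategy) {
  n <- n_cycles(spec)
  ages <- spec$start_age + (seq_len(n) - 1L) * spec$cycle_months / 12
  p_bg <- background_mortality_cycle_prob(spec$lifetable, ages,
                                          spec$cycle_months)
  p_af_adt_raw <- edge_monthly_probs(spec, strategy, "ADT_FREE", "ADT")
  p_adt_crpc_raw <- edge_monthly_probs(spec, strategy, "ADT", "CRPC")
  p_crpc_pca <- edge_monthly_probs(spec, strategy, "CRPC", "DEATH")

  list(
    p_bg = p_bg,
    p_af_adt = p_af_adt_raw * (1 - p_bg),
    p_adt_crpc = p_adt_crpc_raw * (1 - p_bg),
    ## competing independent risks in CRPC: background + PCa-specific
    p_crpc_death = 1 - (1 - p_bg) * (1 - p_crpc_pca)
  )
}

#' Build the transition matrix for one cycle
#'
#' Rows and columns are ordered `ADT_FREE`, `ADT`, `CRPC`, `DEATH`.  Allowed
#' arrows are ADT_FREE to ADT, ADT to CRPC, any alive state to DEATH and the
#' self-loops; DEATH is absorbing.  Background mortality applies to every
#' alive state; prostate-cancer-specific death only from CRPC.  Disease
#' transitions act on the survivors of the cycle's death risk, and the
#' residual mass stays in the current state.
#'
#' @param spec A valid `mdt_spec`.
#' @param strategy Strategy label.
#' @param cycle_index Integer in `[0, horizon)` (0-based, as cycle `t`
#'   governs the step from `t` to `t+1`).
#' @return A 4x4 row-stochastic matrix with `dimnames` the state labels.
#' @export
build_transition_matrix <- function(spec, strategy, cycle_index) {
  strategy <- match.arg(strategy, MDT_STRATEGIES)
  n <- n_cycles(spec)
  if (cycle_index < 0 || cycle_index >= n)
    stop("cycle_index must be in [0, ", n, ")", call. = FALSE)
  dyn <- strategy_dynamics(spec, strategy)
  t <- cycle_index + 1L

  P <- matrix(0, 4, 4, dimnames = list(MDT_STATES, MDT_STATES))
  P["ADT_FREE", "ADT"] <- dyn$p_af_adt[t]
  P["ADT_FREE", "DEATH"] <- dyn$p_bg[t]
  P["ADT", "CRPC"] <- dyn$p_adt_crpc[t]
  P["ADT", "DEATH"] <- dyn$p_bg[t]
  P["CRPC", "DEATH"] <- dyn$p_crpc_death[t]
  P["DEATH", "DEATH"] <- 1
  off <- rowSums(P) - diag(P)
  if (any(off > 1 + 1e-12))
    stop("competing transition probabilities exceed 1 from state ",
         paste(MDT_STATES[off > 1 + 1e-12], collapse = ", "),
         " at cycle ", cycle_index, call. = FALSE)
  diag(P) <- diag(P) + (1 - rowSums(P))
  P
}
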