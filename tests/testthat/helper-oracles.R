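## Independent oracles used across the suite.  These read the raw spec
## tables and re-derive everything from first principles, so they share no
## code path with the cohort engine they check.

## base spec without the placeholder warning
quiet_preset <- function(preset, seed = 1) {
  make_paramset(preset, seed = seed, quiet = TRUE)
}

## deterministic outcome pair as plain lists (for economics tests)
outcome_point <- function(cost, qaly, strategy = NA_character_) {
  list(discounted_cost = cost, discounted_qaly = qaly, strategy = strategy)
}

## ---------------------------------------------------------------------------
## Micro-simulation oracle: n_paths individual patient trajectories through
## the four-state chain, with per-path discounted cost/QALY accumulation.
## Returns means and standard errors.

oracle_microsim <- function(spec, strategy, n_paths = 1e5, seed = 42) {
  set.seed(seed)
  H <- spec$horizon_months
  states <- c("ADT_FREE", "ADT", "CRPC", "DEATH")

  ## monthly hazards straight from the tables
  ages <- spec$start_age + (0:(H - 1)) / 12
  li <- match(floor(ages), spec$lifetable$age)
  qx <- spec$lifetable$qx[li] * (1 - spec$lifetable$pca_fraction[li])
  p_bg <- 1 - (1 - qx)^(1 / 12)
  monthly <- function(from, to) {
    p <- numeric(H)
    tr <- spec$transitions
    rows <- tr[(tr$strategy %in% c(strategy, "ALL")) & tr$from == from &
               tr$to == to, , drop = FALSE]
    for (k in seq_len(nrow(rows)))
      p[(rows$start[k] + 1):rows$end[k]] <-
        1 - (1 - rows$prob[k])^(1 / (rows$end[k] - rows$start[k]))
    p
  }
  p_af <- monthly("ADT_FREE", "ADT")
  p_ac <- monthly("ADT", "CRPC")
  p_cd <- monthly("CRPC", "DEATH")  # PCa-specific component

  ## per-state monthly cost (incl. ADT drug and monthly toxicity management)
  tox <- spec$toxicities
  tox_adt <- sum(tox$prob[tox$context == "ADT"] *
                 tox$rate[tox$context == "ADT"] *
                 tox$cost[tox$context == "ADT"])
  tox_mdt <- sum(tox$prob[tox$context == "MDT"] *
                 tox$rate[tox$context == "MDT"] *
                 tox$cost[tox$context == "MDT"])
  sm <- spec$costs$state_monthly
  mc <- function(st) {
    rows <- sm[(sm$strategy %in% c(strategy, "ALL")) & sm$state == st, ]
    if (nrow(rows)) sum(rows$cost) else 0
  }
  cvec <- c(mc("ADT_FREE"),
            mc("ADT") + spec$costs$adt_drug_monthly + tox_adt,
            mc("CRPC") + tox_adt, 0)
  u <- spec$utilities
  u_af <- if (!is.null(u$adt_free_split))
    spec$sbrt_fraction * u$adt_free_split$sbrt +
      (1 - spec$sbrt_fraction) * u$adt_free_split$surgery else u$adt_free
  uvec <- c(u_af, u$adt, u$crpc, 0)

  ev <- spec$costs$events
  first_mdt <- if (!is.null(ev$first_month_mdt)) ev$first_month_mdt else
    ev$mdt_workup + spec$sbrt_fraction * ev$sbrt_course +
      (1 - spec$sbrt_fraction) * ev$surgery_course

  entry <- if (strategy == "IMMEDIATE_ADT") 2L else 1L
  state <- rep(entry, n_paths)
  cost_acc <- numeric(n_paths)
  qaly_acc <- numeric(n_paths)
  df_c <- (1 + spec$discount$costs)^(-((0:(H - 1)) + 0.5) / 12)
  df_e <- (1 + spec$discount$effects)^(-((0:(H - 1)) + 0.5) / 12)

  for (t in 1:H) {
    r <- stats::runif(n_paths)
    new <- state
    s1 <- state == 1L
    new[s1 & r < p_bg[t]] <- 4L
    new[s1 & r >= p_bg[t] &
        r < p_bg[t] + (1 - p_bg[t]) * p_af[t]] <- 2L
    s2 <- state == 2L
    new[s2 & r < p_bg[t]] <- 4L
    new[s2 & r >= p_bg[t] &
        r < p_bg[t] + (1 - p_bg[t]) * p_ac[t]] <- 3L
    s3 <- state == 3L
    p_d3 <- 1 - (1 - p_bg[t]) * (1 - p_cd[t])
    new[s3 & r < p_d3] <- 4L

    ## trapezoidal state rewards
    qaly_acc <- qaly_acc + (uvec[state] + uvec[new]) / 2 / 12 * df_e[t]
    cyc_cost <- (cvec[state] + cvec[new]) / 2
    ## flow-attached events
    cyc_cost <- cyc_cost + (s1 & new == 2L) * ev$adt_initiation
    if (strategy == "MDT") {
      if (t == 1L) cyc_cost <- cyc_cost + first_mdt + tox_mdt
      else cyc_cost <- cyc_cost + s1 * spec$repeat_mdt_monthly_prob *
          (ev$repeat_mdt + tox_mdt)
    }
    if (strategy == "IMMEDIATE_ADT" && t == 1L)
      cyc_cost <- cyc_cost + ev$adt_initiation
    cost_acc <- cost_acc + cyc_cost * df_c[t]
    state <- new
  }
  list(mean_cost = mean(cost_acc), se_cost = stats::sd(cost_acc) / sqrt(n_paths),
       mean_qaly = mean(qaly_acc), se_qaly = stats::sd(qaly_acc) / sqrt(n_paths))
}
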