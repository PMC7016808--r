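test_that("two-state toy model decays geometrically", {
  spec <- quiet_preset("toy_two_state")
  tr <- run_cohort(spec, "SURVEILLANCE")
  expect_equal(tr$membership[, "ADT_FREE"], 0.5^(0:60), tolerance = 1e-12)
  expect_equal(tr$membership[, "DEATH"], 1 - 0.5^(0:60), tolerance = 1e-12)
  ## expected discounted life with utility one and no discounting:
  ## trapezoidal sum of 0.5^t is 1.5 months = 0.125 QALYs (minus the
  ## negligible truncated tail)
  out <- accumulate_outcomes(tr, spec)
  expect_equal(out$discounted_qaly, 1.5 / 12, tolerance = 1e-10)
  expect_equal(out$discounted_cost, 0)
})

test_that("certain death in the first cycle empties the cohort", {
  spec <- quiet_preset("toy_two_state")
  spec$lifetable$qx <- 1
  tr <- run_cohort(spec, "SURVEILLANCE")
  expect_equal(unname(tr$membership[2, ]), c(0, 0, 0, 1))
})

test_that("full health for five years is exactly 5 QALYs", {
  spec <- mdtcea:::toy_closed_form_spec(monthly_cost = 0, utility = 1,
                                        rate_costs = 0, rate_effects = 0)
  out <- accumulate_outcomes(run_cohort(spec, "SURVEILLANCE"), spec)
  expect_equal(out$discounted_qaly, 5, tolerance = 1e-12)
  expect_equal(out$discounted_cost, 0)
})

test_that("discounted totals match the closed-form annuity", {
  spec <- quiet_preset("toy_closed_form")
  analytic <- attr(spec, "analytic")
  out <- accumulate_outcomes(run_cohort(spec, "SURVEILLANCE"), spec)
  expect_equal(out$discounted_cost, analytic$discounted_cost,
               tolerance = 1e-10)
  expect_equal(out$discounted_qaly, analytic$discounted_qaly,
               tolerance = 1e-10)
})

test_that("cohort mass is conserved and death is monotone", {
  for (seed in 1:5) {
    spec <- quiet_preset("random_valid", seed = seed)
    for (strategy in spec$strategies) {
      m <- run_cohort(spec, strategy)$membership
      expect_equal(unname(rowSums(m)), rep(1, 61), tolerance = 1e-10)
      expect_true(all(diff(m[, "DEATH"]) >= -1e-15))
      expect_true(all(m >= -1e-15))
    }
  }
})

test_that("the loop equals the matrix-power closed form when homogeneous", {
  ## flat life table + whole-horizon transition rows => time-homogeneous
  spec <- quiet_preset("stomp_base")
  spec$lifetable$qx <- 0.02
  spec$transitions <- data.frame(
    strategy = c("MDT", "SURVEILLANCE", "ALL", "ALL"),
    from = c("ADT_FREE", "ADT_FREE", "ADT", "CRPC"),
    to = c("ADT", "ADT", "CRPC", "DEATH"),
    start = 0, end = 60,
    prob = c(0.8, 0.9, 0.7, 0.6))
  for (strategy in c("MDT", "IMMEDIATE_ADT")) {
    P <- build_transition_matrix(spec, strategy, 0)
    m <- run_cohort(spec, strategy)$membership
    m0 <- m[1, ]
    Pt <- diag(4)
    for (t in 1:60) {
      Pt <- Pt %*% P
      expect_equal(m[t + 1, ], drop(m0 %*% Pt), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("discounting never increases a discounted total", {
  spec <- quiet_preset("stomp_base")
  base <- run_all_strategies(spec)
  for (rate in c(0.05, 0.1)) {
    sp <- spec
    sp$discount$costs <- rate
    sp$discount$effects <- rate
    out <- run_all_strategies(sp)
    for (s in names(out)) {
      expect_lt(out[[s]]$discounted_cost, base[[s]]$discounted_cost)
      expect_lt(out[[s]]$discounted_qaly, base[[s]]$discounted_qaly)
    }
  }
  ## and discounted <= undiscounted at the base rates
  for (s in names(base)) {
    expect_lte(base[[s]]$discounted_cost, base[[s]]$undiscounted_cost)
    expect_lte(base[[s]]$discounted_qaly, base[[s]]$undiscounted_qaly)
    expect_lte(base[[s]]$discounted_qaly, 5)
  }
})

test_that("cohort expectations agree with a micro-simulation of paths", {
  spec <- quiet_preset("stomp_base")
  for (strategy in c("MDT", "SURVEILLANCE")) {
    cohort <- accumulate_outcomes(run_cohort(spec, strategy), spec)
    sim <- oracle_microsim(spec, strategy, n_paths = 1e5, seed = 99)
    expect_lt(abs(cohort$discounted_cost - sim$mean_cost), 3 * sim$se_cost)
    expect_lt(abs(cohort$discounted_qaly - sim$mean_qaly), 3 * sim$se_qaly)
  }
})

test_that("immediate ADT enters the model in the ADT state", {
  spec <- quiet_preset("stomp_base")
  tr <- run_cohort(spec, "IMMEDIATE_ADT")
  expect_equal(unname(tr$membership[1, ]), c(0, 1, 0, 0))
  ## deterministic reruns are identical
  out1 <- run_all_strategies(spec)
  out2 <- run_all_strategies(spec)
  expect_identical(out1, out2)
})

test_that("trace export carries cycles, occupancy and cumulative totals", {
  spec <- quiet_preset("stomp_base")
  tr <- run_cohort(spec, "MDT")
  tab <- trace_table(tr, spec)
  expect_identical(nrow(tab), 61L)
  out <- accumulate_outcomes(tr, spec)
  expect_equal(tab$cum_disc_cost[60], out$discounted_cost)
  expect_equal(tab$cum_disc_qaly[60], out$discounted_qaly)
})
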