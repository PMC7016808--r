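test_that("tornado recovers the base ICER at a unit multiplier", {
  spec <- quiet_preset("stomp_base")
  base <- compute_icer(
    accumulate_outcomes(run_cohort(spec, "MDT"), spec),
    accumulate_outcomes(run_cohort(spec, "SURVEILLANCE"), spec))$icer
  noop <- one_way_tornado(spec, low = 1, high = 1)
  expect_equal(attr(noop, "base_icer"), base)
  expect_equal(noop$icer_low, rep(base, nrow(noop)), tolerance = 1e-9)
  expect_equal(noop$icer_high, rep(base, nrow(noop)), tolerance = 1e-9)
})

test_that("tornado rows are sorted, clamped at bounds, and flag no-ops", {
  spec <- quiet_preset("stomp_base")
  ## a cost only immediate ADT pays cannot move the MDT-vs-surveillance ICER
  spec$costs$state_monthly <- rbind(
    spec$costs$state_monthly,
    data.frame(strategy = "IMMEDIATE_ADT", state = "ADT_FREE", cost = 500))
  tor <- one_way_tornado(spec, pair = c("MDT", "SURVEILLANCE"))
  expect_true(all(diff(tor$range) <= 1e-9))
  ## utilities near one are clamped rather than pushed past the bound
  expect_true(tor$clamped[tor$parameter == "u_adt_free"])
  idle <- tor[tor$parameter == "c_state_immediate_adt_adt_free", ]
  expect_true(idle$zero_impact)
  expect_equal(idle$range, 0, tolerance = 1e-9)
  ## the ADT-free utility is the dominant driver: lowering it erodes the
  ## QALY gain of deferring ADT, so the ICER rises steeply
  expect_identical(tor$parameter[1], "u_adt_free")
  expect_gt(tor$icer_low[tor$parameter == "u_adt_free"],
            1.5 * attr(tor, "base_icer"))
})

test_that("cost thresholds: bisection agrees with the affine closed form", {
  spec <- quiet_preset("stomp_base")
  for (param in c("first_month_mdt", "sbrt_course")) {
    th <- cost_threshold_search(spec, param)
    expect_true(th$feasible)
    expect_lt(abs(th$threshold - th$closed_form), 1)
    ## just under the threshold is cost-effective; just over is not
    below <- mdtcea:::set_cost_value(spec, param, th$threshold - 2)
    above <- mdtcea:::set_cost_value(spec, param, th$threshold + 2)
    expect_true(is_cost_effective(mdtcea:::pair_icer(
      below, c("MDT", "SURVEILLANCE")), spec$wtp))
    expect_false(is_cost_effective(mdtcea:::pair_icer(
      above, c("MDT", "SURVEILLANCE")), spec$wtp))
  }
})

test_that("threshold at WTP = base ICER is the base-case cost (fixed point)", {
  spec <- quiet_preset("stomp_base")
  base_icer <- mdtcea:::pair_icer(spec, c("MDT", "SURVEILLANCE"))$icer
  th <- cost_threshold_search(spec, "first_month_mdt", wtp = base_icer)
  expect_equal(th$threshold, first_month_mdt_cost(spec), tolerance = 1e-3)
})

test_that("a dominated strategy has no feasible cost threshold", {
  spec <- quiet_preset("stomp_base")
  th <- cost_threshold_search(spec, "adt_initiation",
                              pair = c("IMMEDIATE_ADT", "MDT"))
  expect_false(th$feasible)
  expect_true(is.na(th$threshold))
})

test_that("effect scaling spans trial effect to no effect", {
  spec <- quiet_preset("stomp_base")
  scan <- effect_scaling_scan(spec, scales = c(1, 0.8, 0.6, 0.4, 0.2, 0))
  expect_identical(nrow(scan), 6L)
  base <- mdtcea:::pair_icer(spec, c("MDT", "SURVEILLANCE"))
  ## s = 1 reproduces the base case bit-exactly
  expect_identical(scan$icer[1], base$icer)
  expect_identical(scan$delta_cost[1], base$delta_cost)
  ## s = 0: MDT transitions equal surveillance's, the QALY gain vanishes
  expect_equal(scan$delta_qaly[6], 0, tolerance = 1e-12)
  ## ICER is non-increasing in the effect size over the NE quadrant
  ne <- scan$classification == "tradeoff_NE"
  expect_true(all(diff(scan$icer[ne]) >= 0))  # scales are decreasing
  ## hazard-scale interpolation is also the identity at s = 1
  scan_h <- effect_scaling_scan(spec, scales = c(1, 0.5),
                                scale_on = "hazard")
  expect_identical(scan_h$icer[1], base$icer)
  expect_error(effect_scaling_scan(spec, scales = c(1.2)), "\\[0,1\\]")
})

test_that("the SE scan is seeded and covers the requested magnitudes", {
  spec <- quiet_preset("stomp_base")
  s1 <- se_scenario_scan(spec, se_values = c(0.05, 0.15), n = 40, seed = 6)
  s2 <- se_scenario_scan(spec, se_values = c(0.05, 0.15), n = 40, seed = 6)
  expect_identical(s1, s2)
  expect_identical(s1$se, c(0.05, 0.15))
  expect_true(all(s1$prob_cost_effective >= 0 & s1$prob_cost_effective <= 1))
})
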