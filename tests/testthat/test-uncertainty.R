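test_that("moment matching recovers the requested parameterisation", {
  g <- moment_match("gamma", 100, 20)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 4)
  b <- moment_match("beta", 0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  expect_error(moment_match("beta", 0.5, 0.5), "infeasible")
  expect_error(moment_match("beta", 1.2, 0.1), "in \\(0,1\\)")
  expect_error(moment_match("gamma", 100, 0), "> 0")
})

test_that("large samples recover the requested mean and SE", {
  set.seed(5)
  n <- 1e6
  for (d in list(moment_match("gamma", 100, 20),
                 moment_match("beta", 0.5, 0.1),
                 moment_match("beta", 0.92, 0.05))) {
    x <- draw_dist(d, n)
    expect_lt(abs(mean(x) - d$mean), 3 * d$se / sqrt(n))
    ## SE of a sample SD is ~ sd/sqrt(2n) for near-normal summaries
    expect_lt(abs(stats::sd(x) - d$se), 3 * d$se / sqrt(2 * n))
  }
})

test_that("parameter draws are seeded, capped and collapse as SE -> 0", {
  spec <- quiet_preset("stomp_base")
  set.seed(7); d1 <- draw_parameter_set(spec)
  set.seed(7); d2 <- draw_parameter_set(spec)
  expect_identical(attr(d1, "psa_draws"), attr(d2, "psa_draws"))

  ## utility ordering cap: force wide CRPC utility uncertainty
  un <- default_uncertainty(spec)
  un$se[un$parameter == "u_crpc"] <- 0.2
  sp <- spec; sp$uncertainty <- un
  set.seed(21)
  for (i in 1:50) {
    ds <- attr(draw_parameter_set(sp), "psa_draws")
    expect_lte(ds[["u_crpc"]], ds[["u_adt"]])
    expect_lte(ds[["u_adt"]], ds[["u_adt_free"]])
  }

  ## SE -> 0: the perturbed spec approaches the base spec
  un0 <- default_uncertainty(spec)
  un0$se <- pmax(1e-9 * un0$mean, 1e-12)
  sp0 <- spec; sp0$uncertainty <- un0
  set.seed(3)
  ds <- draw_parameter_set(sp0)
  base_vals <- param_table(spec)$value
  drawn_vals <- param_table(ds)$value
  expect_equal(drawn_vals, base_vals, tolerance = 1e-6)
})

test_that("run_psa is reproducible and consistent with its summaries", {
  spec <- quiet_preset("stomp_base")
  d1 <- run_psa(spec, n = 60, seed = 12)
  d2 <- run_psa(spec, n = 60, seed = 12)
  expect_identical(d1$cost, d2$cost)
  expect_identical(d1$params, d2$params)

  s <- psa_summary(d1, c("MDT", "SURVEILLANCE"))
  cv <- ceac(d1, c("MDT", "SURVEILLANCE"), wtp_grid = c(0, spec$wtp, 1e7))
  ## CEAC at the configured WTP equals the summary probability exactly
  expect_identical(cv$prob_cost_effective[2], s$prob_cost_effective)
  ## grid end points: pure cost sign / pure QALY sign
  inc_dc <- d1$cost[, "MDT"] - d1$cost[, "SURVEILLANCE"]
  inc_dq <- d1$qaly[, "MDT"] - d1$qaly[, "SURVEILLANCE"]
  expect_equal(cv$prob_cost_effective[1], mean(inc_dc < 0))
  expect_equal(cv$prob_cost_effective[3], mean(inc_dq > 0))
  ## quadrant fractions partition the draws
  expect_equal(sum(s$quadrant_fractions), 1)
})

test_that("degenerate draws collapse to the deterministic point", {
  spec <- quiet_preset("stomp_base")
  un <- default_uncertainty(spec)
  un$se <- pmax(1e-9 * un$mean, 1e-12)
  spec$uncertainty <- un
  det <- run_all_strategies(spec)
  d <- run_psa(spec, n = 20, seed = 2)
  for (s in spec$strategies) {
    expect_equal(d$cost[, s], rep(det[[s]]$discounted_cost, 20),
                 tolerance = 1e-5)
    expect_equal(d$qaly[, s], rep(det[[s]]$discounted_qaly, 20),
                 tolerance = 1e-5)
  }
  ## the pairwise CEAC becomes a step at the deterministic ICER
  det_icer <- compute_icer(det$MDT, det$SURVEILLANCE)$icer
  cv <- ceac(d, c("MDT", "SURVEILLANCE"),
             wtp_grid = c(det_icer - 500, det_icer + 500))
  expect_equal(cv$prob_cost_effective, c(0, 1))
  ## and the summary reproduces the deterministic increments
  s <- psa_summary(d, c("MDT", "SURVEILLANCE"))
  expect_equal(s$icer_ratio_of_means, det_icer, tolerance = 1e-4)
})

test_that("multi-strategy CEAC partitions probability across strategies", {
  spec <- quiet_preset("stomp_base")
  d <- run_psa(spec, n = 80, seed = 9)
  mc <- multi_ceac(d, wtp_grid = seq(0, 80000, by = 20000))
  sums <- unname(rowSums(mc[, spec$strategies]))
  expect_equal(sums, rep(1, nrow(mc)))
  expect_true(all(as.matrix(mc[, spec$strategies]) >= 0))

  ## a single-strategy model is trivially always best
  toy <- quiet_preset("toy_two_state")
  d1 <- run_psa(toy, n = 10, seed = 4)
  mc1 <- multi_ceac(d1, wtp_grid = c(0, 40000))
  expect_equal(mc1$SURVEILLANCE, c(1, 1))
})
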