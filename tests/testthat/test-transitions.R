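test_that("prob_from_median puts cumulative survival at one half", {
  ## frozen values from solving (1-p)^median = 0.5
  expect_equal(prob_from_median(21, 1), 1 - 0.5^(1 / 21))
  expect_equal(prob_from_median(13, 1), 1 - 0.5^(1 / 13))
  expect_equal(prob_from_median(1, 1), 0.5)
  ## verify by cumulative product of monthly survival
  for (med in c(21, 13, 7)) {
    p <- prob_from_median(med, 1)
    expect_equal((1 - p)^med, 0.5, tolerance = 1e-12)
  }
  expect_error(prob_from_median(0), "> 0")
  expect_error(prob_from_median(-3), "> 0")
})

test_that("interval_to_cycle_prob compounds back to the interval", {
  expect_equal(interval_to_cycle_prob(0.5, 6, 1), 1 - 0.5^(1 / 6))
  expect_equal(interval_to_cycle_prob(0, 6, 1), 0)
  expect_equal(interval_to_cycle_prob(1, 6, 1), 1)
  set.seed(11)
  for (p in stats::runif(25)) {
    pc <- interval_to_cycle_prob(p, 6, 1)
    expect_equal(1 - (1 - pc)^6, p, tolerance = 1e-12)
  }
  expect_error(interval_to_cycle_prob(1.2, 6, 1), "\\[0,1\\]")
  expect_error(interval_to_cycle_prob(0.5, 6, 4), "divide")
})

test_that("annual_to_cycle_discount compounds twelve months to one year", {
  expect_equal(annual_to_cycle_discount(0.03, 1), 1.03^(1 / 12) - 1)
  expect_equal(annual_to_cycle_discount(0.015, 1), 1.015^(1 / 12) - 1)
  expect_equal(annual_to_cycle_discount(0, 1), 0)
  for (r in c(0.015, 0.03, 0.08))
    expect_equal((1 + annual_to_cycle_discount(r, 1))^12, 1 + r,
                 tolerance = 1e-12)
  expect_error(annual_to_cycle_discount(-0.01), ">= 0")
})

test_that("background mortality removes the prostate-cancer fraction", {
  lt <- data.frame(age = 60:70, qx = 0.02, pca_fraction = 0.05)
  expect_equal(background_mortality_cycle_prob(lt, 65, 1),
               1 - (1 - 0.02 * 0.95)^(1 / 12))
  ## 12-fold compounding recovers the adjusted annual probability
  p <- background_mortality_cycle_prob(lt, 65, 1)
  expect_equal(1 - (1 - p)^12, 0.019, tolerance = 1e-12)
  lt0 <- data.frame(age = 60:70, qx = 0, pca_fraction = 0.3)
  expect_equal(background_mortality_cycle_prob(lt0, 62, 1), 0)
  lt1 <- data.frame(age = 60:70, qx = 1, pca_fraction = 0)
  expect_equal(background_mortality_cycle_prob(lt1, 62, 1), 1)
  expect_error(background_mortality_cycle_prob(lt, 90, 1), "outside")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  for (seed in 1:5) {
    spec <- quiet_preset("random_valid", seed = seed)
    for (strategy in spec$strategies) {
      for (cyc in c(0L, 7L, 30L, 59L)) {
        P <- build_transition_matrix(spec, strategy, cyc)
        expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
        expect_true(all(P >= 0 & P <= 1))
        expect_equal(unname(P["DEATH", ]), c(0, 0, 0, 1))
        ## only the allowed arrows
        expect_identical(P["ADT_FREE", "CRPC"], 0)
        expect_identical(P["ADT", "ADT_FREE"], 0)
        expect_identical(P["CRPC", "ADT_FREE"], 0)
      }
    }
  }
  spec <- quiet_preset("stomp_base")
  expect_error(build_transition_matrix(spec, "MDT", 60), "cycle_index")
})

test_that("a null model yields the identity matrix", {
  spec <- mdtcea:::toy_closed_form_spec()   # no deaths, no progression
  P <- build_transition_matrix(spec, "SURVEILLANCE", 10)
  expect_equal(unname(P), diag(4))
})

test_that("base-case entry equals the block probability thinned by survival", {
  spec <- quiet_preset("stomp_base")
  P <- build_transition_matrix(spec, "MDT", 0)
  p_block <- interval_to_cycle_prob(1 - 0.5^(6 / 21), 6, 1)
  qx <- spec$lifetable$qx[spec$lifetable$age == 68]
  pca <- spec$lifetable$pca_fraction[spec$lifetable$age == 68]
  p_bg <- 1 - (1 - qx * (1 - pca))^(1 / 12)
  expect_equal(P["ADT_FREE", "ADT"], p_block * (1 - p_bg), tolerance = 1e-14)
  expect_equal(P["ADT_FREE", "DEATH"], p_bg, tolerance = 1e-14)
})

test_that("raising a progression probability cannot reduce exits from ADT-free", {
  spec <- quiet_preset("stomp_base")
  base_af <- run_cohort(spec, "MDT")$membership[61, "ADT_FREE"]
  for (mult in c(1.2, 1.5, 2)) {
    sp <- spec
    i <- which(sp$transitions$strategy == "MDT" & sp$transitions$start == 0)
    sp$transitions$prob[i] <- min(1, sp$transitions$prob[i] * mult)
    af <- run_cohort(sp, "MDT")$membership[61, "ADT_FREE"]
    expect_lte(af, base_af + 1e-12)
    base_af <- af
  }
})
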