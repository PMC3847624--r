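# The cause-structured residual engine: multipliers, percent reductions,
# attribution, decompositions, and the micro-simulation oracle.

test_that("cause multiplier is the residual-risk ratio product", {
  eff <- unit_eff()  # potency 0.5 on malaria
  # hand-computed: (1 - 0.5*0.6) / (1 - 0.5*0.2) = 0.7 / 0.9
  expect_equal(cause_multiplier("malaria", c(tx = 0.2), c(tx = 0.6), eff),
               0.7 / 0.9)
  expect_equal(cause_multiplier("diarrhea", c(tx = 0.2), c(tx = 0.6), eff), 1)
  expect_equal(cause_multiplier("malaria", c(tx = 0.4), c(tx = 0.4), eff), 1)
  sat <- data.frame(intervention_id = "tx", cause = "malaria",
                    effectiveness = 1, affected_fraction = 1)
  expect_error(cause_multiplier("malaria", c(tx = 1), c(tx = 1), sat),
               "saturation")
})

test_that("cause multiplier is invariant to intervention order", {
  set.seed(31)
  for (i in 1:20) {
    cfg <- random_engine_config(4)
    cz <- names(cfg$causes)[1]
    m1 <- cause_multiplier(cz, cfg$baseline, cfg$scenario, cfg$effectiveness)
    shuffled <- cfg$effectiveness[sample(nrow(cfg$effectiveness)), ]
    m2 <- cause_multiplier(cz, cfg$baseline, cfg$scenario, shuffled)
    expect_equal(m1, m2)
  }
})

test_that("percent reduction mixes cause multipliers by the death fractions", {
  eff <- unit_eff()
  causes1 <- cause_structure(c(malaria = 1))
  expect_equal(percent_reduction(causes1, c(tx = 0.2), c(tx = 0.6), eff),
               100 * (1 - 0.7 / 0.9))
  # unchanged coverage gives exactly zero (the fixed-coverage scenario)
  expect_identical(percent_reduction(causes1, c(tx = 0.2), c(tx = 0.2), eff),
                   0)
  # multiplier view is consistent
  expect_equal(mortality_multiplier(causes1, c(tx = 0.2), c(tx = 0.6), eff),
               0.7 / 0.9)
})

test_that("reduction is monotone in coverage and bounded by the addressed cause share", {
  set.seed(41)
  for (i in 1:30) {
    cfg <- random_engine_config()
    R <- percent_reduction(cfg$causes, cfg$baseline, cfg$scenario,
                           cfg$effectiveness)
    # bound: cannot beat the share of deaths from causes touched
    addressed <- sum(cfg$causes[names(cfg$causes) %in%
                                  cfg$effectiveness$cause])
    expect_lte(R, 100 * addressed + 1e-9)
    # monotonicity: push one intervention higher
    iv <- sample(names(cfg$scenario), 1)
    bumped <- cfg$scenario
    bumped[iv] <- min(1, bumped[iv] + 0.1)
    R2 <- percent_reduction(cfg$causes, cfg$baseline, bumped,
                            cfg$effectiveness)
    expect_gte(R2, R - 1e-12)
  }
})

test_that("coverage declines yield negative reductions", {
  eff <- unit_eff()
  R <- percent_reduction(cause_structure(c(malaria = 1)),
                         c(tx = 0.6), c(tx = 0.2), eff)
  expect_lt(R, 0)
})

test_that("attributable reduction is the scenario difference in percentage points", {
  expect_equal(attributable_reduction(22, 8), 14)
  expect_equal(attributable_reduction(5, 5), 0)
  expect_equal(attributable_reduction(10, 15), -5)
})

test_that("single-intervention decompositions equal the joint reduction", {
  eff <- unit_eff()
  causes <- cause_structure(c(malaria = 0.4))
  joint <- percent_reduction(causes, c(tx = 0.2), c(tx = 0.6), eff)
  iso <- decompose_by_intervention(causes, c(tx = 0.2), c(tx = 0.6), eff,
                                   "isolation")
  sim <- decompose_by_intervention(causes, c(tx = 0.2), c(tx = 0.6), eff,
                                   "simultaneous")
  expect_equal(unname(iso), joint)
  expect_equal(unname(sim), joint)
})

test_that("interventions on disjoint causes decompose separably", {
  eff <- data.frame(
    intervention_id = c("a", "b"), cause = c("malaria", "diarrhea"),
    effectiveness = c(0.8, 0.9), affected_fraction = c(0.5, 0.6))
  causes <- cause_structure(c(malaria = 0.3, diarrhea = 0.2))
  base <- c(a = 0.1, b = 0.2); scen <- c(a = 0.5, b = 0.7)
  iso <- decompose_by_intervention(causes, base, scen, eff, "isolation")
  sim <- decompose_by_intervention(causes, base, scen, eff, "simultaneous")
  expect_equal(sim, iso)
  # and shares reproduce the direct per-cause computation
  expect_equal(unname(sim["a"]),
               100 * 0.3 * (1 - (1 - 0.4 * 0.5) / (1 - 0.4 * 0.1)))
})

test_that("simultaneous shares conserve the joint reduction; isolation is super-additive", {
  set.seed(53)
  for (i in 1:25) {
    cfg <- random_engine_config(sample(2:4, 1))
    joint <- percent_reduction(cfg$causes, cfg$baseline, cfg$scenario,
                               cfg$effectiveness)
    sim <- decompose_by_intervention(cfg$causes, cfg$baseline, cfg$scenario,
                                     cfg$effectiveness, "simultaneous")
    expect_equal(sum(sim), joint, tolerance = 1e-9)
    iso <- decompose_by_intervention(cfg$causes, cfg$baseline, cfg$scenario,
                                     cfg$effectiveness, "isolation")
    expect_gte(sum(iso), joint - 1e-9)  # sub-additivity of the joint effect
  }
})

test_that("unchanged coverage decomposes to all zeros", {
  cfg <- random_engine_config()
  for (mode in c("isolation", "simultaneous")) {
    d <- decompose_by_intervention(cfg$causes, cfg$baseline, cfg$baseline,
                                   cfg$effectiveness, mode)
    expect_equal(unname(d), rep(0, length(d)))
  }
})

test_that("microsim oracle is seeded, reproducible, and centered on zero under no change", {
  eff <- unit_eff()
  causes <- cause_structure(c(malaria = 1))
  a <- microsim_oracle(causes, c(tx = 0.3), c(tx = 0.3), eff,
                       n_children = 2e4, seed = 9)
  b <- microsim_oracle(causes, c(tx = 0.3), c(tx = 0.3), eff,
                       n_children = 2e4, seed = 9)
  expect_identical(a, b)
  expect_lte(abs(a$estimate), 3 * a$se)

  tiny1 <- microsim_oracle(causes, c(tx = 0.3), c(tx = 0.6), eff, 10, seed = 4)
  tiny2 <- microsim_oracle(causes, c(tx = 0.3), c(tx = 0.6), eff, 10, seed = 4)
  expect_identical(tiny1, tiny2)
})

test_that("microsim oracle agrees with the analytic reduction on the worked example", {
  eff <- unit_eff()
  causes <- cause_structure(c(malaria = 1))
  est <- microsim_oracle(causes, c(tx = 0.2), c(tx = 0.6), eff,
                         n_children = 2e5, seed = 17)
  analytic <- 100 * (1 - 0.7 / 0.9)
  expect_lte(abs(est$estimate - analytic), 3 * est$se)
  expect_gt(est$se, 0)
})
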