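# The three counterfactual coverage scenarios: extrapolation, capping,
# target attainment, continuation, and donor-rate substitution.

test_that("annual rate of change is the coverage difference per year", {
  expect_equal(annual_rate(2006, 0.20, 2010, 0.40), 0.05)
  expect_equal(annual_rate(2003, 0.30, 2010, 0.30), 0)
  expect_error(annual_rate(2012, 0.3, 2010, 0.3), "precede")
})

test_that("fixed-coverage scenario holds the baseline value at every year", {
  expect_equal(unname(build_fixed(0.26)), rep(0.26, 4))
  expect_equal(unname(build_fixed(0)), rep(0, 4))
  expect_equal(unname(build_fixed(1)), rep(1, 4))
  expect_named(build_fixed(0.5), as.character(2010:2013))
})

test_that("scale-up runs linearly from baseline to hit the target exactly in 2013", {
  act <- build_scale_up(0.26, 0.70)
  expect_equal(act[["2013"]], 0.70)
  expect_equal(act[["2010"]], 0.26)
  expect_equal(act[["2011"]], 0.26 + (0.70 - 0.26) / 3)  # on the line
  expect_equal(act[["2013"]] - act[["2010"]], 0.44)

  vita <- build_scale_up(0.89, 0.90)
  expect_equal(vita[["2013"]], 0.90)
})

test_that("pre-achieved targets continue at the prior rate, floored and capped", {
  expect_equal(unname(build_scale_up(0.95, 0.90, prior_rate = 0)),
               rep(0.95, 4))
  # negative prior rates never pull coverage down
  expect_equal(unname(build_scale_up(0.95, 0.90, prior_rate = -0.05)),
               rep(0.95, 4))
  # continuation is ceilinged at max(cap, baseline)
  cont <- build_scale_up(0.85, 0.80, prior_rate = 0.04)
  expect_equal(unname(cont), c(0.85, 0.89, 0.90, 0.90))
})

test_that("secular trend extends the prior rate and stops at the cap", {
  capped <- build_secular(0.80, 0.05)
  expect_equal(capped[["2013"]], 0.90)  # uncapped 0.95
  expect_equal(capped[["2011"]], 0.85)
  expect_equal(unname(build_secular(0.80, 0)), rep(0.80, 4))
  floored <- build_secular(0.10, -0.05)
  expect_equal(floored[["2013"]], 0)
  # a baseline already above the cap is not dragged down
  expect_equal(unname(build_secular(0.95, 0.02)), rep(0.95, 4))
})

test_that("scenario trajectories stay in [0,1] and obey their shape invariants", {
  set.seed(23)
  spec <- scenario_spec()
  for (i in 1:300) {
    b <- runif(1); tg <- runif(1); r <- runif(1, -0.3, 0.3)
    su <- build_scale_up(b, tg, r, spec)
    sec <- build_secular(b, r, spec)
    fx <- build_fixed(b, spec)
    expect_true(all(c(su, sec, fx) >= 0 & c(su, sec, fx) <= 1))
    expect_true(all(sec <= max(spec$cap, b) + 1e-12))
    if (r >= 0) expect_true(all(diff(sec) >= -1e-12))
    if (b < tg) {
      expect_equal(su[["2013"]], tg)
      expect_equal(unname(diff(su)), rep((tg - b) / 3, 3))  # linearity
    }
  }
})

test_that("donor-rate substitution replaces recipients, leaves others, and is idempotent", {
  spec <- scenario_spec(rate_substitutions = c(act = "antibiotics"))
  rates <- c(act = 0, antibiotics = 0.03, ors = 0.015)
  out <- substitute_rate(rates, spec)
  expect_equal(out[["act"]], 0.03)
  expect_equal(out[["ors"]], 0.015)
  expect_equal(substitute_rate(out, spec), out)
  expect_equal(substitute_rate(rates, scenario_spec()), rates)
  expect_error(
    substitute_rate(c(act = 0), scenario_spec(rate_substitutions = c(act = "absent"))),
    "absent donor")
})

test_that("projection enumeration is the deterministic unit-by-scenario product", {
  units14 <- c(sprintf("d%d", 1:9), "r1", "r2", "g1", "g2", "all")
  jobs <- enumerate_projections(units14)
  expect_equal(nrow(jobs), 42L)
  expect_equal(jobs$unit_id[1:3], rep("d1", 3))
  expect_equal(jobs$scenario[1:3], c("fixed", "scale_up", "secular_trend"))
  expect_equal(nrow(enumerate_projections("solo")), 3L)
  expect_error(enumerate_projections(character(0)), "no units")
  expect_error(enumerate_projections("u", "bogus"), "unknown scenario")
})

test_that("build_scenarios holds non-program interventions fixed in scale-up", {
  s <- rbind(
    two_anchor_surveys("u1", "program_iv", ref = c(2006, 0.2), base = 0.4),
    two_anchor_surveys("u1", "nonprogram_iv", ref = c(2006, 0.1), base = 0.3))
  spec <- scenario_spec(targets = c(program_iv = 0.8))
  long <- build_scenarios(harmonize_surveys(s), spec)
  su <- long[long$scenario == "scale_up", ]
  expect_equal(su$coverage[su$intervention_id == "program_iv" &
                             su$year == 2013], 0.8)
  expect_equal(su$coverage[su$intervention_id == "nonprogram_iv" &
                             su$year == 2013], 0.3)
  # secular trend still moves the non-program intervention
  sec <- long[long$scenario == "secular_trend", ]
  expect_equal(sec$coverage[sec$intervention_id == "nonprogram_iv" &
                              sec$year == 2013], 0.3 + 0.05 * 3)
})
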