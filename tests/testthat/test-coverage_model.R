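# Harmonization of heterogeneous survey anchors: source preference,
# SBA recomputation, the flat-trend conflict rule, and interpolation.

test_that("reference selection prefers the more recent survey and is order-invariant", {
  both <- survey_estimates("u1", "itn", c(2003, 2006),
                           c("DHS2003", "MICS2006"), c(0.30, 0.40))
  expect_equal(select_reference(both)$coverage, 0.40)
  expect_equal(select_reference(both)$source, "MICS2006")
  expect_equal(select_reference(both[2:1, ]), select_reference(both),
               ignore_attr = TRUE)

  only_dhs <- survey_estimates("u1", "itn", 2003, "DHS2003", 0.30)
  expect_equal(select_reference(only_dhs)$coverage, 0.30)

  expect_error(select_reference(both[0, ]), "no reference data")
  expect_error(select_reference(rbind(only_dhs, only_dhs)), "ambiguous")
  expect_error(
    select_reference(survey_estimates("u1", "itn", 2010, "BASELINE2010", 0.5)),
    "not a valid reference")
})

test_that("skilled birth attendance counts doctor, nurse, midwife only", {
  bd <- c(doctor = 0.05, nurse = 0.10, midwife = 0.15, matrone = 0.20)
  expect_equal(recompute_sba(bd), 0.30)
  expect_equal(recompute_sba(c(doctor = 0, nurse = 0, midwife = 0)), 0)
  # auxiliary midwives and other attendants are excluded too
  expect_equal(recompute_sba(c(doctor = 0.1, nurse = 0.1, midwife = 0.1,
                               auxiliary_midwife = 0.3, other = 0.2)), 0.3)
  expect_error(recompute_sba(c(doctor = 0.6, nurse = 0.6)), "more than 1")
  # the provider-sum rule is generic over categories
  expect_equal(recompute_sba(bd, included = c("doctor", "matrone")), 0.25)
})

test_that("apparent pre-baseline declines collapse to a flat trend at the baseline value", {
  flat <- resolve_decline(c(2006, 0.50), c(2010, 0.30))
  expect_equal(flat$coverage, c(0.30, 0.30))
  expect_true(attr(flat, "conflict"))

  kept <- resolve_decline(c(2006, 0.20), c(2010, 0.30))
  expect_equal(kept$coverage, c(0.20, 0.30))
  expect_false(attr(kept, "conflict"))

  equal_anchors <- resolve_decline(c(2003, 0.30), c(2010, 0.30))
  expect_equal(equal_anchors$coverage, c(0.30, 0.30))
  expect_false(attr(equal_anchors, "conflict"))

  expect_error(resolve_decline(c(2012, 0.3), c(2010, 0.3)), "precede")
})

test_that("resolved anchors are non-decreasing and within [0, 1] for random inputs", {
  set.seed(11)
  for (i in 1:200) {
    ref <- c(sample(2003:2009, 1), runif(1))
    base <- c(2010, runif(1))
    out <- resolve_decline(ref, base)
    expect_true(all(out$coverage >= 0 & out$coverage <= 1))
    expect_true(diff(out$coverage) >= 0)  # declines always removed
  }
})

test_that("interpolation is linear, exact at anchors, and refuses extrapolation", {
  a <- data.frame(year = c(2006, 2010), coverage = c(0.20, 0.40))
  expect_equal(interpolate_coverage(a, 2008), 0.30)
  expect_equal(interpolate_coverage(a, 2010), 0.40)
  expect_error(interpolate_coverage(a, 2012), "outside anchor span")

  set.seed(7)
  for (i in 1:50) {
    yrs <- sort(sample(2003:2013, sample(2:5, 1)))
    cov <- runif(length(yrs))
    anch <- data.frame(year = yrs, coverage = cov)
    # anchor exactness
    expect_equal(interpolate_coverage(anch, yrs), cov)
    # betweenness on every segment midpoint-ish query
    q <- runif(1, min(yrs), max(yrs))
    v <- interpolate_coverage(anch, q)
    seg <- findInterval(q, yrs, rightmost.closed = TRUE)
    expect_gte(v, min(cov[seg], cov[seg + 1]))
    expect_lte(v, max(cov[seg], cov[seg + 1]))
  }
})

test_that("proxy coverage maps a linked indicator through a scaling factor", {
  expect_equal(proxy_coverage(0.71, "SBA"), 0.71)
  expect_equal(proxy_coverage(0.80, "ANC4plus", factor = 0.5), 0.40)
  expect_equal(proxy_coverage(0, "SBA", factor = 0.3), 0)
  expect_error(proxy_coverage(0.5, "unknown_link"))
})

test_that("harmonization derives anchors and rates per unit and intervention", {
  s <- rbind(
    two_anchor_surveys("u1", "rising", ref = c(2006, 0.20), base = 0.40),
    two_anchor_surveys("u1", "declining", ref = c(2006, 0.50), base = 0.30),
    survey_estimates("u1", "unmeasured_before", 2010, "BASELINE2010", 0.25)
  )
  h <- harmonize_surveys(s)
  rising <- h[h$intervention_id == "rising", ]
  expect_equal(rising$rate, 0.05)
  expect_false(rising$conflict)

  declining <- h[h$intervention_id == "declining", ]
  expect_equal(declining$rate, 0)
  expect_equal(declining$ref_coverage, 0.30)
  expect_true(declining$conflict)

  fallback <- h[h$intervention_id == "unmeasured_before", ]
  expect_equal(fallback$rate, 0)
  expect_true(fallback$no_reference)

  # duplicated baseline rows are rejected
  dup_base <- s[s$source == "BASELINE2010" & s$intervention_id == "rising", ]
  expect_error(harmonize_surveys(rbind(s, dup_base)), "exactly one baseline")
})

test_that("proxy links copy estimates from the linked indicator", {
  s <- two_anchor_surveys("u1", "sba", ref = c(2006, 0.5), base = 0.71)
  out <- apply_proxy_links(s, list(mgso4 = list(of = "sba", link = "SBA",
                                                factor = 1.0)))
  mg <- out[out$intervention_id == "mgso4", ]
  expect_equal(nrow(mg), 2L)
  expect_equal(mg$coverage, c(0.5, 0.71))
  expect_error(apply_proxy_links(s, list(x = list(of = "absent", link = "SBA"))),
               "no survey estimates")
})
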