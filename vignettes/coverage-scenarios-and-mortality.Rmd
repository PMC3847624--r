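---
title: "Coverage scenarios and under-five mortality: the listlite model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage scenarios and under-five mortality: the listlite model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listlite)
```

## The problem

Child-survival programs scale up a basket of proven interventions —
malaria treatment with artemisinin combination therapy (ACT), oral
rehydration solution (ORS) and zinc for diarrhea, oral antibiotics for
pneumonia, insecticide-treated nets, antenatal and delivery care — and need
a forward-looking estimate of the under-five mortality reduction the
scale-up can deliver, and of how much of that reduction is attributable to
the program rather than to pre-existing trends. `listlite` implements the
deterministic projection logic used for such estimates in the Lives Saved
Tool (LiST) family of models: coverage trajectories in, cause-structured
mortality multipliers out.

The intended setting is a program evaluation with three survey anchors per
intervention: a DHS-style national survey around 2003, a MICS-style national
survey around 2006, and a district-representative program baseline survey in
2010, with program targets set for 2013.

## Harmonizing survey anchors

Coverage is stored internally as a fraction in $[0,1]$; all file I/O and
rendered tables use percent, which is how survey reports print coverage.
Time runs on integer calendar years (a year value means mid-year status),
because the source surveys themselves resolve only to survey years.

Three rules reconcile the anchors for each unit and intervention:

* **Recency preference.** When both a 2003 DHS-style and a 2006 MICS-style
  estimate exist, the MICS-style one is used (`select_reference()`); two
  estimates from the same source are an error rather than a silent choice.
* **SBA recomputation.** Skilled birth attendance is recomputed from the
  provider breakdown as doctor + nurse + midwife, excluding auxiliary
  midwives and trained traditional birth attendants ("matrones"), whose
  inclusion in older reports conflicts with the current indicator
  definition (`recompute_sba()`). The rule is exposed as a generic
  provider-category sum because nothing about it is SBA-specific.
* **Flat-trend conflict rule.** If the (national) reference value exceeds
  the (local) 2010 baseline value, the apparent decline is treated as a
  representativeness artifact, not a real trend: the reference value is
  discarded and the pre-2010 trend is flat at the 2010 value
  (`resolve_decline()`). A unit with no reference estimate at all gets the
  same flat fallback — the conservative choice, since it zeroes the secular
  trend rather than inventing one.

Between anchors, coverage changes linearly (`interpolate_coverage()`, which
delegates to `stats::approx` and refuses to extrapolate — extending beyond
2010 is a scenario rule, not an interpolation). Interventions not measurable
in household surveys (magnesium sulfate, active management of the third
stage of labor) take the coverage of a linked indicator, ANC4+ or SBA,
scaled by a configurable factor (`proxy_coverage()`). The default factor of
1 is a documented placeholder: the linkage coefficients used inside full
LiST are not public, and we preferred an explicit identity to a guessed
constant.

## The three scenarios

All scenarios run on the horizon 2010–2013 and are emitted at integer years
only; the mortality engine consumes the endpoint (2010 and 2013) values, so
sub-annual resolution would add nothing.

* **Fixed coverage**: every intervention held at its 2010 value. This is the
  null scenario; its percent reduction is exactly zero by construction (the
  engine is a ratio model), which the tests assert identically.
* **Scale-up**: program interventions move linearly from their 2010 value to
  hit their 2013 target exactly; non-program interventions stay at 2010
  values. Where the target was already achieved at baseline, coverage
  continues at the pre-2010 annual rate instead. We additionally floor that
  continuation rate at zero and ceiling the result at
  $\max(\text{cap}, \text{baseline})$: continuation rules must be total even
  for units with declining or saturated coverage, and reusing the secular
  cap keeps the two extrapolating scenarios consistent.
* **Secular trend**: every intervention continues at its pre-2010 annual
  rate $r_i = (C_i(2010) - C_i(t_{ref}))/(2010 - t_{ref})$, clamped below at
  0 and above at $\max(\text{cap}, C_i(2010))$. The cap defaults to 90%:
  once a secular trend reaches it, coverage stops rising. Negative rates are
  allowed here (coverage may genuinely decline); the conflict rule upstream
  removes most of them.

One intervention-specific wrinkle is handled by **donor-rate substitution**
(`substitute_rate()`): ACTs were introduced only around 2006 (replacing
chloroquine), so their own pre-2010 "trend" is uninformative; the shipped
configuration substitutes the oral-antibiotics rate, and the mechanism is a
general recipient-to-donor map.

## The mortality engine

Let $f_c$ be the fraction of under-five deaths from cause $c$ (the bundled
structure: malaria 24%, pneumonia 18%, diarrhea 12%, neonatal 22%, other
24% — an explicit `other` residual closes the sum to 1). Each intervention
$i$ acting on cause $c$ has an effectiveness $E_{ic}$ and an affected
fraction $A_{ic}$; their product is its potency. Interventions combine
multiplicatively on residual risk (independent action, the standard LiST
convention):

$$M_c = \prod_i \frac{1 - E_{ic} A_{ic} C_i^{scen}}{1 - E_{ic} A_{ic} C_i^{base}},
\qquad R = 100\Big(1 - \sum_c f_c M_c\Big).$$

This residual-*ratio* formulation (multiplier relative to baseline coverage)
was chosen over an "impact on deaths" subtraction so that $R = 0$ at
baseline is exact and baseline saturation ($1 - E A C^{base} \le 0$) is an
explicit error rather than a silent negative. A single under-five pool is
modeled — no age bands, cohort aging, or month-by-month demography — because
the quantity of interest is the total percent reduction between the horizon
endpoints, which this ratio engine reproduces structurally. Consequences:
$R = 0$ exactly under fixed coverage, $R$ can be negative under coverage
decline (reported, not clamped), and $R$ can never exceed 100 times the
death share of the causes any intervention touches. Vaccine herd effects,
maternal outcomes, stillbirths, and nutrition-status feedbacks are out of
scope.

Two decompositions are provided (`decompose_by_intervention()`):
*isolation* moves one intervention at a time (the values are sub-additive:
interventions sharing a cause compete for the same deaths); *simultaneous*
attributes each cause's log-multiplier to interventions — exact, because
$\log M_c = \sum_i \log m_{ic}$ under the multiplicative model — and maps
back to the percent scale, so the shares sum to the joint $R$ to machine
precision. A cause whose multiplier is exactly 1 contributes nothing and
gets zero shares, which also covers the degenerate cancellation case.
Program-attributable reduction is plain scenario differencing:
scale-up $R$ minus secular-trend $R$, in percentage points, sign preserved.

## The micro-simulation oracle

`microsim_oracle()` validates the analytic engine by brute force: per arm it
simulates `n_children` children, assigns each a potential cause of death
with probability $f_c$, draws receipt of each intervention acting on that
cause as an independent Bernoulli event at the arm's coverage, and lets each
received intervention avert the death independently with probability
$E A$. Because $f_c$ describes the distribution of *deaths at baseline*,
the estimator mixes per-cause death-rate **ratios**,
$\hat R = 100(1 - \sum_c f_c\, \hat q_c^{scen}/\hat q_c^{base})$, which is
the quantity that converges to the analytic $R$; mixing absolute simulated
death probabilities would not. The Monte-Carlo standard error comes from the
delta method on the per-cause binomial variances. The oracle embodies the
same independent-action assumption as the engine — it validates the
algebra and the implementation, not the assumption itself. The acceptance
suite checks agreement within 3 standard errors on 20 random configurations
at $10^6$ children per arm, a size chosen to make the Monte-Carlo error a
fraction of a percentage point while keeping the whole check under a couple
of minutes on one CPU.

## The synthetic generator and the bundled study

`generate_study()` draws, per unit and intervention, a 2010 baseline and a
pre-2010 secular rate, back-computes the 2003/2006 anchors from them, and
with probability `conflict_prob` (default 0.2, so the branch is routinely
exercised) draws the reference *above* the baseline to force the flat-trend
rule. Ground-truth reductions for all three scenarios are computed
analytically from the true effectiveness table at generation time, so the
full pipeline can be tested for exact parameter recovery. Defaults mirror
the emulated study design: 9 districts in 2 regions, 2 intervention-group
pseudo-units, and all districts pooled — 14 units, hence 42 projections.
Pooled pseudo-units get independent coverage draws rather than aggregates
recomputed from districts, matching how a pooled survey stratum is actually
analyzed; district heterogeneity is independent uniform noise, with no
attempt to mimic a real correlation structure. Households and sampling
variance are not simulated: the pipeline consumes point estimates, as the
analysis it implements does.

`burkina_fixture()` bundles the published pooled baselines and 2013 targets
for twelve accelerated interventions and the cause structure above, in the
14-unit layout. Two components are synthetic stand-ins, labelled as such in
their filenames: the national 2003/2006 reference anchors (the published
annex with district microdata is not available; the vitamin A reference is
deliberately placed above its 2010 baseline so the conflict rule fires, and
ACTs carry no reference so the donor substitution is exercised) and the
effectiveness table (the calibrated database inside full LiST is not
public). Mortality results from the fixture are therefore meaningful in
structure and ordering — treatment interventions dominate, ACT > ORS >
antibiotics, scale-up exceeds secular trend, capping every target at 90%
beats the original targets — but are not numeric reproductions of any
published table. Where the published sources disagree internally (an
antibiotics target printed as 60% in one table and 50% in another; cause
fractions summing to 54% in one section against a 49% statement in
another), the fixtures follow the table used for the gap arithmetic and the
itemized fractions, respectively.

## Numerical choices and limitations

* Exact checks (anchor exactness, target attainment, zero reduction under
  fixed coverage, decomposition conservation) are asserted at $10^{-9}$ or
  identically; scenario clamps use closed intervals, so a baseline already
  at the cap stays put.
* Ties and degenerate inputs: equal reference and baseline values are "no
  conflict, flat anyway"; an empty substitution map is the identity;
  `substitute_rate()` is idempotent; a cause with no acting intervention has
  multiplier exactly 1.
* Reported tables store full precision; rounding to whole percent is left
  to presentation, so rounding anomalies in rendered tables are explainable
  but never baked into stored results.
* The linearity assumption is known to be wrong for campaign-driven
  interventions (bed-net distributions move in steps); like the model this
  package follows, no intervention-specific scale-up shapes are
  implemented. No uncertainty intervals are produced: inputs are point
  estimates and the engine is deterministic; the seeded oracle quantifies
  only its own Monte-Carlo error, not input uncertainty.
* Passing tests on synthetic studies show the pipeline implements its own
  stated rules exactly; they cannot show that the independent-action
  assumption, the proxy-identity default, or a synthetic effectiveness
  table describe any real population.

## A worked run

```{r run}
study <- burkina_fixture()
run <- run_pipeline(study)
run$table2_like[run$table2_like$unit_id == "all_districts", ]
head(run$table3_like[order(-run$table3_like$isolation_R),
                     c("intervention_id", "baseline_percent",
                       "target_percent", "gap_percent", "isolation_R")], 4)
```

```{r sensitivity}
s <- sensitivity_all_to_cap(study, cap = 0.90)
s[s$unit_id == "all_districts", ]
```
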