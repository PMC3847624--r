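#' Cause-of-death structure for under-five mortality
#'
#' Fractions of under-five deaths by cause.  An explicit `other` residual is
#' added (or checked) so the fractions sum to exactly 1; interventions that
#' touch no cause leave `other` mortality unchanged.
#'
#' @param fractions Named numeric vector of cause fractions in \[0, 1\].  If
#'   no `other` entry is present and the fractions sum to less than 1, the
#'   residual is added as `other`.
#' @return Named numeric vector of class `"cause_structure"` summing to 1.
#' @examples
#' cause_structure(c(malaria = 0.24, pneumonia = 0.18, diarrhea = 0.12,
#'                   neonatal = 0.22))
#' @export
cause_structure <- function(fractions) {
  assert_fraction(fractions, "cause fractions")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("cause fractions must be named", call. = FALSE)
  }
  if (anyDuplicated(names(fractions))) {
    stop("duplicate cause names", call. = FALSE)
  }
  tot <- sum(fractions)
  if (!("other" %in% names(fractions))) {
    if (tot > 1 + 1e-9) stop("cause fractions sum to more than 1", call. = FALSE)
    fractions <- c(fractions, other = max(0, 1 - tot))
  } else if (abs(tot - 1) > 1e-9) {
    stop("cause fractions (including 'other') must sum to 1", call. = FALSE)
  }
  structure(fractions, class = "cause_structure")
}

#' Validate an intervention-effectiveness table
#'
#' Each row links one intervention to one cause of death with an
#' effectiveness (proportional mortality reduction among those affected and
#' covered) and an affected fraction (share of the cause's deaths the
#' intervention can act on).  Their product is the intervention's potency
#' against the cause.
#'
#' @param x Data frame with columns `intervention_id`, `cause`,
#'   `effectiveness`, `affected_fraction`.
#' @return The validated data frame with a `potency` column added.
#' @export
effectiveness_table <- function(x) {
  needed <- c("intervention_id", "cause", "effectiveness", "affected_fraction")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("effectiveness table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  assert_fraction(x$effectiveness, "effectiveness")
  assert_fraction(x$affected_fraction, "affected_fraction")
  if (anyDuplicated(x[, c("intervention_id", "cause")])) {
    stop("duplicate (intervention, cause) rows in effectiveness table",
         call. = FALSE)
  }
  x$potency <- x$effectiveness * x$affected_fraction
  x
}

#' Residual mortality multiplier for one cause
#'
#' Interventions acting on a cause combine multiplicatively on residual risk
#' (independent-action assumption, the standard LiST convention): the
#' scenario-to-baseline mortality multiplier for cause *c* is
#' \deqn{M_c = \prod_i \frac{1 - E_i A_i C_i^{scen}}{1 - E_i A_i C_i^{base}}}
#' over interventions *i* with an effectiveness entry on *c*.  An empty
#' product gives 1.
#'
#' @param cause Cause identifier.
#' @param baseline_cov,scenario_cov Named coverage-fraction vectors by
#'   intervention id.
#' @param effectiveness An [effectiveness_table()].
#' @return Positive multiplier; 1 when no intervention acts on the cause or
#'   scenario coverage equals baseline coverage.
#' @export
cause_multiplier <- function(cause, baseline_cov, scenario_cov,
                             effectiveness) {
  effectiveness <- effectiveness_table(effectiveness)
  entries <- effectiveness[effectiveness$cause == cause, , drop = FALSE]
  m <- 1
  for (i in seq_len(nrow(entries))) {
    iv <- entries$intervention_id[i]
    if (!(iv %in% names(baseline_cov))) next  # intervention absent from study
    p <- entries$potency[i]
    denom <- 1 - p * baseline_cov[[iv]]
    if (denom <= 0) {
      stop(sprintf("baseline saturation: intervention '%s' on cause '%s' leaves no residual mortality",
                   iv, cause), call. = FALSE)
    }
    cs <- if (iv %in% names(scenario_cov)) scenario_cov[[iv]] else
      baseline_cov[[iv]]
    m <- m * (1 - p * cs) / denom
  }
  m
}

#' Percent reduction in under-five mortality for a scenario
#'
#' The overall mortality multiplier is the cause-fraction-weighted mean of
#' the per-cause residual multipliers, and the percent reduction is
#' \deqn{R = 100 (1 - \sum_c f_c M_c).}
#' R is 0 exactly when scenario coverage equals baseline coverage, can be
#' negative when coverage declines, and can never exceed 100 times the share
#' of deaths from causes any intervention touches.
#'
#' @inheritParams cause_multiplier
#' @param causes A [cause_structure()].
#' @return Percent reduction (0-100 scale).
#' @export
percent_reduction <- function(causes, baseline_cov, scenario_cov,
                              effectiveness) {
  causes <- cause_structure(unclass(causes))
  mult <- vapply(names(causes), function(cz) {
    cause_multiplier(cz, baseline_cov, scenario_cov, effectiveness)
  }, numeric(1))
  100 * (1 - sum(causes * mult))
}

#' Mortality multiplier for a scenario
#'
#' @inheritParams percent_reduction
#' @return The ratio of scenario to baseline under-five mortality,
#'   `1 - percent_reduction/100`.
#' @export
mortality_multiplier <- function(causes, baseline_cov, scenario_cov,
                                 effectiveness) {
  1 - percent_reduction(causes, baseline_cov, scenario_cov,
                        effectiveness) / 100
}

#' Program-attributable reduction by scenario differencing
#'
#' The scale-up scenario's percent reduction minus the secular-trend
#' scenario's, in percentage points: an approximation of the mortality
#' reduction attributable to the program over and above pre-existing trends.
#' May be negative.
#'
#' @param scale_up_R,secular_R Percent reductions from the two scenarios for
#'   the same unit and engine inputs.
#' @return Difference in percentage points.
#' @examples
#' attributable_reduction(22, 8)  # 14
#' @export
attributable_reduction <- function(scale_up_R, secular_R) {
  scale_up_R - secular_R
}

#' Per-intervention decomposition of the mortality reduction
#'
#' Two decompositions of a scenario's mortality reduction by intervention:
#'
#' * `isolation`: for each intervention, the percent reduction when only that
#'   intervention moves to its scenario coverage and all others stay at
#'   baseline.  Isolation values need not sum to the joint reduction
#'   (they are sub-additive under the multiplicative model).
#' * `simultaneous`: each intervention's share of the joint reduction.  For
#'   each cause, the cause's log-multiplier decomposes exactly as the sum of
#'   the interventions' individual log-multipliers, so intervention *i*
#'   receives the fraction \eqn{\log m_{ic} / \log M_c} of the cause's
#'   contribution \eqn{f_c (1 - M_c)}.  Shares sum to the joint reduction.
#'
#' @inheritParams percent_reduction
#' @param mode `"isolation"` or `"simultaneous"`.
#' @return Named numeric vector of percent reductions by intervention id.
#' @export
decompose_by_intervention <- function(causes, baseline_cov, scenario_cov,
                                      effectiveness,
                                      mode = c("isolation", "simultaneous")) {
  mode <- match.arg(mode)
  causes <- cause_structure(unclass(causes))
  effectiveness <- effectiveness_table(effectiveness)
  ivs <- names(baseline_cov)
  if (mode == "isolation") {
    out <- vapply(ivs, function(iv) {
      solo <- baseline_cov
      if (iv %in% names(scenario_cov)) solo[[iv]] <- scenario_cov[[iv]]
      percent_reduction(causes, baseline_cov, solo, effectiveness)
    }, numeric(1))
    return(out)
  }
  # simultaneous: cause-wise log-multiplier attribution
  out <- stats::setNames(numeric(length(ivs)), ivs)
  for (cz in names(causes)) {
    m_ic <- vapply(ivs, function(iv) {
      solo_scen <- baseline_cov
      if (iv %in% names(scenario_cov)) solo_scen[[iv]] <- scenario_cov[[iv]]
      cause_multiplier(cz, baseline_cov, solo_scen, effectiveness)
    }, numeric(1))
    M_c <- prod(m_ic)
    logM <- log(M_c)
    if (abs(logM) < 1e-12) next  # cause untouched (or exactly cancelled)
    w <- log(m_ic) / logM
    out <- out + 100 * causes[[cz]] * (1 - M_c) * w
  }
  out
}

#' Assemble a projection result record
#'
#' @param unit_id,scenario Identifiers for the projection.
#' @param percent_reduction Percent reduction 2010 -> 2013.
#' @param per_intervention Optional named vector of per-intervention percent
#'   reductions.
#' @param u5mr_2010 Optional baseline under-five mortality rate (deaths per
#'   1,000 live births) used only to scale absolute deaths averted; percent
#'   reductions never depend on it.
#' @return A list of class `"projection_result"` with the mortality
#'   multiplier (`1 - R/100`) filled in.
#' @export
projection_result <- function(unit_id, scenario, percent_reduction,
                              per_intervention = NULL, u5mr_2010 = NULL) {
  structure(list(
    unit_id = unit_id, scenario = scenario,
    mortality_multiplier = 1 - percent_reduction / 100,
    percent_reduction = percent_reduction,
    per_intervention = per_intervention,
    u5mr_2010 = u5mr_2010
  ), class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projection %s / %s: %.2f%% reduction (multiplier %.4f)\n",
              x$unit_id, x$scenario, x$percent_reduction,
              x$mortality_multiplier))
  invisible(x)
}
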