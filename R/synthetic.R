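#' Specification for a synthetic coverage-scale-up study
#'
#' Describes the study design emulated by [generate_study()]: a set of
#' districts nested in regions, plus pooled pseudo-units for each region,
#' each intervention-group stratum, and all districts together — mirroring a
#' program evaluation in which coverage is measured by household survey at
#' three anchors (2003 DHS-style, 2006 MICS-style, 2010 program baseline)
#' and projected to 2013.  The defaults give the 14-unit structure (9
#' districts + 2 regions + 2 intervention groups + all districts) whose
#' three scenarios yield 42 projections.
#'
#' @param n_districts,n_regions,n_groups Numbers of districts, regions, and
#'   intervention-group pseudo-units.
#' @param interventions Character vector of intervention ids; defaults to the
#'   interventions of [default_effectiveness()].
#' @param anchor_years Survey anchor years; the last is the baseline.
#' @param baseline_coverage_range Range for 2010 baseline coverage draws,
#'   either `c(lo, hi)` for all interventions or a named list per
#'   intervention.
#' @param secular_rate_range Range (fraction/year) for pre-baseline annual
#'   rate draws.
#' @param target_range Range for 2013 target draws (one target per
#'   intervention, shared across units, as program targets are national).
#' @param conflict_prob Probability that a unit-intervention pair's reference
#'   value is drawn *above* its baseline value, exercising the flat-trend
#'   conflict rule.
#' @param both_anchor_prob Probability that both a DHS-style and MICS-style
#'   reference estimate are emitted (the MICS-style one is then preferred).
#' @param true_effectiveness Effectiveness table used both to generate the
#'   ground truth and shipped with the study; default
#'   [default_effectiveness()].
#' @param causes A [cause_structure()]; defaults to the Burkina Faso-like
#'   structure (malaria 24%, pneumonia 18%, diarrhea 12%, neonatal 22%).
#' @param cap Secular-trend coverage cap (fraction).
#' @param rate_substitutions Donor-rate substitution map (see
#'   [scenario_spec()]).
#' @param seed Default seed used by [generate_study()].
#' @return A list of class `"synthetic_study_spec"`.
#' @export
synthetic_study_spec <- function(n_districts = 9L, n_regions = 2L,
                                 n_groups = 2L,
                                 interventions = NULL,
                                 anchor_years = c(2003L, 2006L, 2010L),
                                 baseline_coverage_range = c(0.05, 0.65),
                                 secular_rate_range = c(0, 0.04),
                                 target_range = c(0.5, 0.9),
                                 conflict_prob = 0.2,
                                 both_anchor_prob = 0.3,
                                 true_effectiveness = default_effectiveness(),
                                 causes = default_cause_structure(),
                                 cap = 0.90,
                                 rate_substitutions = NULL,
                                 seed = 1L) {
  true_effectiveness <- effectiveness_table(true_effectiveness)
  if (is.null(interventions)) {
    interventions <- unique(true_effectiveness$intervention_id)
  }
  stopifnot(n_districts >= 1, n_regions >= 1, n_groups >= 0,
            length(interventions) >= 1)
  check_range <- function(r, what, lo = 0, hi = 1) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop(sprintf("'%s' must be an ordered sub-interval of [%g, %g]",
                   what, lo, hi), call. = FALSE)
    }
  }
  if (!is.list(baseline_coverage_range)) {
    check_range(baseline_coverage_range, "baseline_coverage_range")
    baseline_coverage_range <- stats::setNames(
      rep(list(baseline_coverage_range), length(interventions)), interventions)
  } else {
    lapply(names(baseline_coverage_range), function(nm) {
      check_range(baseline_coverage_range[[nm]], nm)
    })
  }
  check_range(secular_rate_range, "secular_rate_range", -1, 1)
  check_range(target_range, "target_range")
  assert_fraction(conflict_prob, "conflict_prob")
  assert_fraction(both_anchor_prob, "both_anchor_prob")
  structure(list(
    n_districts = as.integer(n_districts), n_regions = as.integer(n_regions),
    n_groups = as.integer(n_groups), interventions = interventions,
    anchor_years = as.integer(anchor_years),
    baseline_coverage_range = baseline_coverage_range,
    secular_rate_range = secular_rate_range, target_range = target_range,
    conflict_prob = conflict_prob, both_anchor_prob = both_anchor_prob,
    true_effectiveness = true_effectiveness,
    causes = cause_structure(unclass(causes)), cap = cap,
    rate_substitutions = rate_substitutions, seed = as.integer(seed)
  ), class = "synthetic_study_spec")
}

#' Default synthetic effectiveness table
#'
#' A small, plausible effectiveness/affected-fraction table for generic
#' treatment and prevention interventions against the four leading causes of
#' under-five death.  Values are synthetic round numbers for testing; they
#' are not any model's calibrated database.
#'
#' @return An [effectiveness_table()].
#' @export
default_effectiveness <- function() {
  effectiveness_table(data.frame(
    intervention_id = c("malaria_tx", "bednets", "pneumonia_tx",
                        "diarrhea_ors", "diarrhea_zinc", "neonatal_care"),
    cause = c("malaria", "malaria", "pneumonia",
              "diarrhea", "diarrhea", "neonatal"),
    effectiveness = c(0.95, 0.55, 0.70, 0.90, 0.25, 0.35),
    affected_fraction = c(0.80, 0.90, 0.85, 0.90, 0.90, 0.50),
    stringsAsFactors = FALSE
  ))
}

#' Default cause-of-death structure
#'
#' Malaria 24%, pneumonia 18%, diarrhea 12%, neonatal 22%, with the residual
#' 24% in `other` — the high-mortality Sahelian profile the synthetic
#' studies emulate.
#'
#' @return A [cause_structure()].
#' @export
default_cause_structure <- function() {
  cause_structure(c(malaria = 0.24, pneumonia = 0.18, diarrhea = 0.12,
                    neonatal = 0.22))
}

#' Generate a complete synthetic study with analytic ground truth
#'
#' Draws, for every unit and intervention, a 2010 baseline coverage and a
#' pre-baseline secular rate; back-computes the 2003/2006 reference anchors
#' from them (with probability `conflict_prob` the reference is instead drawn
#' above the baseline, so harmonization must apply the flat-trend rule); and
#' computes the ground-truth percent mortality reduction for all three
#' scenarios directly from the scenario arithmetic and the residual-risk
#' formula, using the spec's true effectiveness table.  Identical spec and
#' seed give bit-identical output.
#'
#' Pooled pseudo-units (regions, intervention groups, all districts) receive
#' their own independent coverage draws, as a pooled survey stratum would.
#'
#' @param spec A [synthetic_study_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of class `"listlite_study"` with elements `surveys`
#'   (a [survey_estimates()] frame), `scenario` (a [scenario_spec()]),
#'   `effectiveness`, `causes`, `units`, `pooled_unit`, and `truth`
#'   (data frame `unit_id`, `scenario`, `percent_reduction`).
#' @export
generate_study <- function(spec = synthetic_study_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  districts <- sprintf("district_%02d", seq_len(spec$n_districts))
  regions <- sprintf("region_%d", seq_len(spec$n_regions))
  groups <- if (spec$n_groups > 0) sprintf("group_%d", seq_len(spec$n_groups))
  units <- c(districts, regions, groups, "all_districts")
  ivs <- spec$interventions
  base_year <- max(spec$anchor_years)
  ref_years <- sort(setdiff(spec$anchor_years, base_year))

  with_seed(seed, {
    targets <- stats::setNames(
      stats::runif(length(ivs), spec$target_range[1], spec$target_range[2]),
      ivs)
    scen_spec <- scenario_spec(targets = targets, cap = spec$cap,
                               rate_substitutions = spec$rate_substitutions,
                               horizon = c(base_year, base_year + 3L))

    rows <- list()
    truth_rows <- list()
    for (u in units) {
      base_cov <- stats::setNames(numeric(length(ivs)), ivs)
      true_rate <- stats::setNames(numeric(length(ivs)), ivs)
      for (iv in ivs) {
        rng <- spec$baseline_coverage_range[[iv]]
        c2010 <- stats::runif(1, rng[1], rng[2])
        drawn_rate <- stats::runif(1, spec$secular_rate_range[1],
                                   spec$secular_rate_range[2])
        conflict <- stats::runif(1) < spec$conflict_prob
        emit_both <- length(ref_years) > 1 &&
          stats::runif(1) < spec$both_anchor_prob
        use_years <- if (emit_both) ref_years else
          ref_years[sample.int(length(ref_years), 1L)]
        anchor_rows <- lapply(use_years, function(y) {
          val <- if (conflict) {
            min(1, c2010 + stats::runif(1, 0.02, 0.15))
          } else {
            min(1, max(0, c2010 - drawn_rate * (base_year - y)))
          }
          src <- if (y == 2003L) "DHS2003" else "MICS2006"
          data.frame(unit_id = u, intervention_id = iv, year = y,
                     source = src, stratum = "rural", coverage = val,
                     stringsAsFactors = FALSE)
        })
        rows <- c(rows, anchor_rows, list(data.frame(
          unit_id = u, intervention_id = iv, year = base_year,
          source = "BASELINE2010", stratum = "rural", coverage = c2010,
          stringsAsFactors = FALSE)))
        # ground-truth rate as harmonization will see it: the preferred
        # (most recent) reference anchor, flattened on conflict
        ref_y <- max(use_years)
        ref_v <- anchor_rows[[which(use_years == ref_y)]]$coverage
        true_rate[iv] <- if (ref_v > c2010) 0 else
          (c2010 - ref_v) / (base_year - ref_y)
        base_cov[iv] <- c2010
      }
      # donor substitution on the true rates
      if (length(scen_spec$rate_substitutions)) {
        subs <- scen_spec$rate_substitutions
        for (recipient in names(subs)) {
          true_rate[recipient] <- true_rate[[subs[[recipient]]]]
        }
      }
      horizon_len <- 3
      scen2013 <- list(
        fixed = base_cov,
        scale_up = stats::setNames(vapply(ivs, function(iv) {
          b <- base_cov[[iv]]; tg <- targets[[iv]]
          if (b < tg) tg else
            min(min(b + max(true_rate[[iv]], 0) * horizon_len,
                    max(spec$cap, b)), 1)
        }, numeric(1)), ivs),
        secular_trend = stats::setNames(vapply(ivs, function(iv) {
          b <- base_cov[[iv]]
          min(max(min(b + true_rate[[iv]] * horizon_len,
                      max(spec$cap, b)), 0), 1)
        }, numeric(1)), ivs)
      )
      f <- as.numeric(spec$causes)
      for (sk in names(scen2013)) {
        mult <- vapply(names(spec$causes), function(cz) {
          entries <- spec$true_effectiveness[
            spec$true_effectiveness$cause == cz &
              spec$true_effectiveness$intervention_id %in% ivs, ,
            drop = FALSE]
          if (nrow(entries) == 0L) return(1)
          prod((1 - entries$potency *
                  scen2013[[sk]][entries$intervention_id]) /
                 (1 - entries$potency * base_cov[entries$intervention_id]))
        }, numeric(1))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          unit_id = u, scenario = sk,
          percent_reduction = 100 * (1 - sum(f * mult)),
          stringsAsFactors = FALSE)
      }
    }
    surveys <- validate_survey_estimates(do.call(rbind, rows))
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    new_study(
      surveys = surveys, scenario = scen_spec,
      effectiveness = spec$true_effectiveness, causes = spec$causes,
      units = units, pooled_unit = "all_districts",
      truth = truth, name = sprintf("synthetic study (seed %d)", seed)
    )
  })
}

new_study <- function(surveys, scenario, effectiveness, causes, units,
                      pooled_unit, truth = NULL, name = "study",
                      u5mr_2010 = NA_real_) {
  structure(list(
    surveys = surveys, scenario = scenario,
    effectiveness = effectiveness_table(effectiveness),
    causes = cause_structure(unclass(causes)),
    units = units, pooled_unit = pooled_unit, truth = truth,
    name = name, u5mr_2010 = u5mr_2010
  ), class = "listlite_study")
}

#' @export
print.listlite_study <- function(x, ...) {
  cat("listlite study:", x$name, "\n")
  cat(sprintf("  %d units, %d interventions, %d survey estimates\n",
              length(x$units),
              length(unique(x$surveys$intervention_id)),
              nrow(x$surveys)))
  cat(sprintf("  horizon %d -> %d, cap %.0f%%\n",
              x$scenario$horizon[1], x$scenario$horizon[2],
              100 * x$scenario$cap))
  if (!is.null(x$truth)) cat("  ground truth available\n")
  invisible(x)
}
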