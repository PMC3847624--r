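#' Scenario specification
#'
#' Bundles the settings that define the three counterfactual coverage
#' scenarios over the projection horizon: the 2013 coverage targets for
#' program interventions (scale-up scenario), the coverage cap applied to
#' secular trends and to post-target continuation, and the map of donor-rate
#' substitutions for interventions whose own pre-baseline trend is
#' uninformative (e.g. ACTs, introduced only shortly before the baseline,
#' borrow the oral-antibiotics rate).
#'
#' @param targets Named numeric vector of 2013 target coverage fractions for
#'   program interventions; required for the scale-up scenario.
#' @param cap Coverage cap as a fraction, default 0.90: once a secular trend
#'   reaches the cap, coverage ceases to increase.
#' @param rate_substitutions Named character vector or list mapping a
#'   recipient intervention id to its donor intervention id.
#' @param horizon Integer `c(start, end)` years, default `c(2010, 2013)`.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(targets = c(act_malaria = 0.70),
#'               rate_substitutions = c(act_malaria = "antibiotics_pneumonia"))
#' @export
scenario_spec <- function(targets = NULL, cap = 0.90,
                          rate_substitutions = NULL,
                          horizon = c(2010L, 2013L)) {
  if (!is.numeric(cap) || length(cap) != 1L || cap <= 0 || cap > 1) {
    stop("cap must be a fraction in (0, 1]", call. = FALSE)
  }
  if (!is.null(targets)) {
    assert_fraction(targets, "targets")
    if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
      stop("targets must be named by intervention id", call. = FALSE)
    }
  }
  horizon <- as.integer(horizon)
  if (length(horizon) != 2L || horizon[1] >= horizon[2]) {
    stop("horizon must be c(start, end) with start < end", call. = FALSE)
  }
  subs <- if (is.null(rate_substitutions)) character(0) else
    unlist(rate_substitutions)
  structure(list(targets = targets, cap = cap,
                 rate_substitutions = subs, horizon = horizon),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario specification\n")
  cat("  horizon:", x$horizon[1], "->", x$horizon[2], "\n")
  cat("  cap:", sprintf("%.0f%%", 100 * x$cap), "\n")
  cat("  program interventions with targets:", length(x$targets), "\n")
  if (length(x$rate_substitutions)) {
    cat("  rate substitutions:",
        paste(names(x$rate_substitutions), "<-", x$rate_substitutions,
              collapse = "; "), "\n")
  }
  invisible(x)
}

.scenario_kinds <- c("fixed", "scale_up", "secular_trend")

#' Pre-baseline annual rate of coverage change
#'
#' @param ref_year Reference anchor year (before the baseline year).
#' @param ref_coverage Coverage fraction at the reference year.
#' @param base_year Baseline year (default 2010).
#' @param base_coverage Coverage fraction at baseline.
#' @return Signed rate in coverage fraction per year; a flat pre-baseline
#'   series yields 0.
#' @examples
#' annual_rate(2006, 0.20, 2010, 0.40)  # 0.05 per year
#' @export
annual_rate <- function(ref_year, ref_coverage, base_year = 2010L,
                        base_coverage) {
  if (ref_year >= base_year) {
    stop("reference year must precede the baseline year", call. = FALSE)
  }
  assert_fraction(ref_coverage, "reference coverage")
  assert_fraction(base_coverage, "baseline coverage")
  (base_coverage - ref_coverage) / (base_year - ref_year)
}

scenario_years <- function(horizon) seq(horizon[1], horizon[2])

named_years <- function(values, years) {
  names(values) <- as.character(years)
  values
}

#' Fixed-coverage scenario segment
#'
#' Holds coverage constant at the baseline (2010) value through the end of
#' the horizon.
#'
#' @param baseline Coverage fraction at the baseline year.
#' @param spec A [scenario_spec()].
#' @return Named numeric vector of coverage by year over the horizon.
#' @export
build_fixed <- function(baseline, spec = scenario_spec()) {
  assert_fraction(baseline, "baseline coverage")
  yrs <- scenario_years(spec$horizon)
  named_years(rep(baseline, length(yrs)), yrs)
}

#' Scale-up scenario segment
#'
#' Program interventions move linearly from their baseline coverage to hit
#' the 2013 target exactly.  Where the target was already achieved at
#' baseline, coverage instead continues at the pre-baseline annual rate
#' (floored at zero — continuation never decreases coverage), subject to a
#' ceiling of `max(cap, baseline)`.
#'
#' @param baseline Coverage fraction at the baseline year.
#' @param target 2013 target coverage fraction.
#' @param prior_rate Pre-baseline annual rate (fraction/year), used only when
#'   the target is pre-achieved.
#' @param spec A [scenario_spec()].
#' @return Named numeric vector of coverage by year over the horizon.
#' @examples
#' build_scale_up(0.26, 0.70)                    # linear to 0.70 in 2013
#' build_scale_up(0.95, 0.90, prior_rate = 0)    # flat at 0.95
#' @export
build_scale_up <- function(baseline, target, prior_rate = 0,
                           spec = scenario_spec()) {
  assert_fraction(baseline, "baseline coverage")
  assert_fraction(target, "target coverage")
  yrs <- scenario_years(spec$horizon)
  if (baseline < target) {
    vals <- baseline + (target - baseline) * (yrs - yrs[1]) /
      (yrs[length(yrs)] - yrs[1])
  } else {
    r <- max(prior_rate, 0)
    ceiling_ <- max(spec$cap, baseline)
    vals <- pmin(baseline + r * (yrs - yrs[1]), ceiling_)
  }
  named_years(pmin(pmax(vals, 0), 1), yrs)
}

#' Secular-trend scenario segment
#'
#' Extends the pre-baseline annual rate of change through the horizon:
#' `c(t) = baseline + rate * (t - 2010)`, clamped below at 0 and above at
#' `max(cap, baseline)` — once a secular trend reaches the cap (default 90%),
#' coverage ceases to increase.
#'
#' @param baseline Coverage fraction at the baseline year.
#' @param rate Annual rate of change (fraction/year), possibly negative.
#' @param spec A [scenario_spec()].
#' @return Named numeric vector of coverage by year over the horizon.
#' @examples
#' build_secular(0.80, 0.05)  # reaches the 90% cap in 2012 and stays there
#' @export
build_secular <- function(baseline, rate, spec = scenario_spec()) {
  assert_fraction(baseline, "baseline coverage")
  yrs <- scenario_years(spec$horizon)
  ceiling_ <- max(spec$cap, baseline)
  vals <- baseline + rate * (yrs - yrs[1])
  named_years(pmin(pmax(pmin(vals, ceiling_), 0), 1), yrs)
}

#' Apply donor-rate substitutions to a rate map
#'
#' Each recipient intervention named in the spec's substitution map takes its
#' donor's annual rate; all other rates pass through unchanged.  Idempotent.
#'
#' @param rates Named numeric vector of annual rates by intervention id.
#' @param spec A [scenario_spec()] whose `rate_substitutions` maps
#'   recipient id -> donor id.
#' @return Named numeric vector of the same shape as `rates`.
#' @examples
#' substitute_rate(c(act_malaria = 0, antibiotics_pneumonia = 0.03),
#'                 scenario_spec(rate_substitutions =
#'                   c(act_malaria = "antibiotics_pneumonia")))
#' @export
substitute_rate <- function(rates, spec) {
  subs <- spec$rate_substitutions
  if (!length(subs)) return(rates)
  missing_donor <- setdiff(unname(subs), names(rates))
  if (length(missing_donor)) {
    stop("rate substitution names absent donor(s): ",
         paste(missing_donor, collapse = ", "), call. = FALSE)
  }
  for (recipient in names(subs)) {
    if (recipient %in% names(rates)) {
      rates[recipient] <- rates[[subs[[recipient]]]]
    }
  }
  rates
}

#' Enumerate projection jobs
#'
#' The Cartesian product of analysis units and scenario kinds, in
#' deterministic order (units in input order; scenarios fixed, scale-up,
#' secular-trend).  A 14-unit study — nine districts, two regions, two
#' intervention-group strata, and all districts pooled — yields 42
#' projections.
#'
#' @param units Character vector of unit ids.
#' @param scenarios Character vector of scenario kinds.
#' @return Data frame with columns `unit_id`, `scenario`.
#' @export
enumerate_projections <- function(units, scenarios = .scenario_kinds) {
  if (!length(units)) stop("no units to project", call. = FALSE)
  if (!length(scenarios)) stop("no scenarios to project", call. = FALSE)
  bad <- setdiff(scenarios, .scenario_kinds)
  if (length(bad)) {
    stop("unknown scenario kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- expand.grid(scenario = scenarios, unit_id = units,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("unit_id", "scenario")]
  rownames(out) <- NULL
  out
}

#' Build all three scenario coverage trajectories from harmonized anchors
#'
#' For each unit and intervention in the harmonized table, constructs the
#' fixed-coverage, scale-up, and secular-trend coverage trajectories over the
#' horizon.  In the scale-up scenario, interventions without a target
#' ("non-program" interventions) are held at their baseline value; program
#' interventions move to target (or continue at their prior rate if the
#' target is pre-achieved).  Secular-trend rates are donor-substituted first.
#'
#' @param harmonized Output of [harmonize_surveys()].
#' @param spec A [scenario_spec()] with targets for program interventions.
#' @return Long data frame: `unit_id`, `scenario`, `intervention_id`, `year`,
#'   `coverage` (fraction).
#' @export
build_scenarios <- function(harmonized, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  units <- unique(harmonized$unit_id)
  yrs <- scenario_years(spec$horizon)
  res <- vector("list", length(units))
  for (k in seq_along(units)) {
    u <- units[k]
    h <- harmonized[harmonized$unit_id == u, , drop = FALSE]
    rates <- stats::setNames(h$rate, h$intervention_id)
    rates <- substitute_rate(rates, spec)
    per_iv <- lapply(seq_len(nrow(h)), function(i) {
      iv <- h$intervention_id[i]
      base <- h$base_coverage[i]
      fixed <- build_fixed(base, spec)
      scale_up <- if (iv %in% names(spec$targets)) {
        build_scale_up(base, spec$targets[[iv]], rates[[iv]], spec)
      } else {
        fixed  # non-program interventions held at baseline
      }
      secular <- build_secular(base, rates[[iv]], spec)
      data.frame(
        unit_id = u,
        scenario = rep(.scenario_kinds, each = length(yrs)),
        intervention_id = iv,
        year = rep(yrs, times = 3L),
        coverage = c(fixed, scale_up, secular),
        stringsAsFactors = FALSE
      )
    })
    res[[k]] <- do.call(rbind, per_iv)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
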