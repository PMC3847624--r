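#' Construct a table of survey coverage estimates
#'
#' A survey estimate records the measured coverage of one intervention in one
#' geographic unit at one survey anchor.  Coverage is stored as a fraction in
#' \[0, 1\]; file readers and writers use percent to match how household-survey
#' reports print coverage.
#'
#' @param unit_id,intervention_id Character identifiers.
#' @param year Integer calendar year, in \[2000, 2015\].
#' @param source Survey source, one of `"DHS2003"`, `"MICS2006"`,
#'   `"BASELINE2010"`.
#' @param coverage Coverage fraction in \[0, 1\].
#' @param stratum Sampling stratum, one of `"rural"`, `"urban"`, `"all"`.
#' @return A `data.frame` with one row per estimate and class
#'   `"survey_estimates"`.
#' @examples
#' survey_estimates("all", "ors_diarrhea", 2010, "BASELINE2010", 0.23)
#' @export
survey_estimates <- function(unit_id, intervention_id, year, source, coverage,
                             stratum = "rural") {
  out <- data.frame(
    unit_id = as.character(unit_id),
    intervention_id = as.character(intervention_id),
    year = as.integer(year),
    source = as.character(source),
    stratum = as.character(stratum),
    coverage = as.numeric(coverage),
    stringsAsFactors = FALSE
  )
  validate_survey_estimates(out)
}

#' @rdname survey_estimates
#' @param x A data frame of survey estimates.
#' @export
validate_survey_estimates <- function(x) {
  needed <- c("unit_id", "intervention_id", "year", "source", "stratum",
              "coverage")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("survey estimates lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  assert_fraction(x$coverage, "coverage")
  if (any(x$year < 2000 | x$year > 2015)) {
    stop("survey years must lie in [2000, 2015]", call. = FALSE)
  }
  bad <- setdiff(unique(x$source), .SURVEY_SOURCES)
  if (length(bad)) {
    stop("unknown survey source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_str <- setdiff(unique(x$stratum), c("rural", "urban", "all"))
  if (length(bad_str)) {
    stop("unknown stratum value(s): ", paste(bad_str, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- unique(c("survey_estimates", class(x)))
  x
}

#' Select the reference (pre-baseline) estimate for one intervention and unit
#'
#' Among pre-baseline survey estimates, the more recently collected survey is
#' preferred: a MICS-style 2006 estimate is used over a DHS-style 2003
#' estimate when both exist.  The baseline-survey source is not a valid
#' reference and is rejected.
#'
#' @param estimates A data frame of survey estimates (see
#'   [survey_estimates()]) for a single intervention and unit, none from the
#'   baseline source.
#' @param prefer_source_order Character vector giving the preference order;
#'   the first source present wins.
#' @return The selected single-row data frame.
#' @examples
#' e <- survey_estimates("all", "itn_irs", c(2003, 2006),
#'                       c("DHS2003", "MICS2006"), c(0.30, 0.40))
#' select_reference(e)$coverage  # 0.40, the MICS value
#' @export
select_reference <- function(estimates,
                             prefer_source_order = c("MICS2006", "DHS2003")) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    stop("no reference data: empty estimate list", call. = FALSE)
  }
  estimates <- validate_survey_estimates(as.data.frame(estimates))
  if (length(unique(estimates$intervention_id)) > 1L ||
      length(unique(estimates$unit_id)) > 1L) {
    stop("reference selection operates on one intervention and unit at a time",
         call. = FALSE)
  }
  if (any(estimates$source == "BASELINE2010")) {
    stop("the baseline survey is not a valid reference source", call. = FALSE)
  }
  if (anyDuplicated(estimates$source)) {
    stop("ambiguous reference: multiple estimates from the same source",
         call. = FALSE)
  }
  for (src in prefer_source_order) {
    hit <- which(estimates$source == src)
    if (length(hit)) return(estimates[hit, , drop = FALSE])
  }
  stop("no reference data: no estimate from a recognized reference source",
       call. = FALSE)
}

#' Recompute skilled birth attendance from a provider breakdown
#'
#' Skilled birth attendance (SBA) under the current definition counts births
#' attended by a doctor, nurse, or midwife, excluding trained traditional
#' birth attendants ("matrones") and auxiliary midwives.  Survey reports that
#' pooled those categories are recomputed from the provider-level breakdown.
#'
#' The rule is exposed generically: any subset of provider categories can be
#' summed via `included`; the default is the SBA definition.
#'
#' @param breakdown Named numeric vector (or one-row data frame) of fractions
#'   of births by attendant category, e.g. `doctor`, `nurse`, `midwife`,
#'   `auxiliary_midwife`, `matrone`, `other`.  Each must lie in \[0, 1\] and
#'   the included categories must sum to at most 1.
#' @param included Character vector of category names to sum.
#' @return The summed coverage fraction.
#' @examples
#' recompute_sba(c(doctor = 0.05, nurse = 0.10, midwife = 0.15, matrone = 0.20))
#' @export
recompute_sba <- function(breakdown,
                          included = c("doctor", "nurse", "midwife")) {
  if (is.data.frame(breakdown)) {
    stopifnot(nrow(breakdown) == 1L)
    breakdown <- unlist(breakdown[1, , drop = TRUE])
  }
  breakdown <- breakdown[!is.na(breakdown)]
  assert_fraction(breakdown, "provider fractions")
  if (sum(breakdown) > 1 + 1e-9) {
    stop("provider fractions sum to more than 1", call. = FALSE)
  }
  present <- intersect(included, names(breakdown))
  total <- sum(breakdown[present])
  if (total > 1 + 1e-9) {
    stop("included provider categories sum to more than 1", call. = FALSE)
  }
  unname(min(total, 1))
}

#' Resolve an apparent pre-baseline coverage decline
#'
#' When the pre-baseline reference estimate exceeds the baseline-survey value,
#' the apparent decline is treated as an artifact of the reference surveys
#' being national rather than local: the baseline value is considered more
#' representative, the reference value is discarded, and the pre-baseline
#' trend is made flat at the baseline value.  Otherwise both anchors are kept
#' unchanged.
#'
#' @param reference Length-2 numeric `c(year, coverage)` or a single-row
#'   survey-estimate data frame, with year before the baseline year.
#' @param baseline Length-2 numeric `c(year, coverage)` at the baseline year.
#' @return A data frame with columns `year`, `coverage` (two rows, the
#'   resolved anchors) and a logical attribute `"conflict"`.
#' @examples
#' resolve_decline(c(2006, 0.50), c(2010, 0.30))  # flattened at 0.30
#' resolve_decline(c(2006, 0.20), c(2010, 0.30))  # kept as-is
#' @export
resolve_decline <- function(reference, baseline) {
  reference <- as_anchor(reference)
  baseline <- as_anchor(baseline)
  if (baseline["year"] != .BASELINE_YEAR) {
    stop("baseline anchor must be at year ", .BASELINE_YEAR, call. = FALSE)
  }
  if (reference["year"] >= baseline["year"]) {
    stop("reference anchor must precede the baseline year", call. = FALSE)
  }
  conflict <- reference["coverage"] > baseline["coverage"]
  ref_cov <- if (conflict) baseline["coverage"] else reference["coverage"]
  out <- data.frame(
    year = as.integer(c(reference["year"], baseline["year"])),
    coverage = as.numeric(c(ref_cov, baseline["coverage"]))
  )
  attr(out, "conflict") <- unname(conflict)
  out
}

as_anchor <- function(x) {
  if (is.data.frame(x)) x <- c(year = x$year[1], coverage = x$coverage[1])
  if (is.null(names(x)) || !all(c("year", "coverage") %in% names(x))) {
    names(x) <- c("year", "coverage")
  }
  assert_fraction(x[["coverage"]], "anchor coverage")
  x
}

#' Linearly interpolate a coverage trajectory between anchors
#'
#' Coverage between survey anchors is assumed to change linearly.  Queries
#' outside the anchor span are refused: extending trajectories beyond the
#' last anchor is the job of the scenario rules, not of interpolation.
#'
#' @param anchors Data frame with columns `year` and `coverage`, at least two
#'   rows, strictly increasing years.
#' @param query_year Integer year(s) within the anchor span.
#' @return Interpolated coverage fraction(s); exact at anchor years.
#' @examples
#' a <- data.frame(year = c(2006, 2010), coverage = c(0.20, 0.40))
#' interpolate_coverage(a, 2008)  # 0.30
#' @export
interpolate_coverage <- function(anchors, query_year) {
  stopifnot(is.data.frame(anchors), nrow(anchors) >= 2L)
  if (any(diff(anchors$year) <= 0)) {
    stop("anchor years must be strictly increasing", call. = FALSE)
  }
  assert_fraction(anchors$coverage, "anchor coverage")
  lo <- min(anchors$year); hi <- max(anchors$year)
  if (any(query_year < lo | query_year > hi)) {
    stop(sprintf("query year outside anchor span [%d, %d]; extrapolation is a scenario rule",
                 lo, hi), call. = FALSE)
  }
  stats::approx(anchors$year, anchors$coverage, xout = query_year,
                method = "linear", ties = "ordered")$y
}

#' Proxy coverage for interventions without direct survey measurement
#'
#' Some interventions (magnesium sulfate for pre-eclampsia, active management
#' of the third stage of labor, ...) are not readily measured in household
#' surveys; their coverage is assigned from a measured linked indicator —
#' four-plus antenatal visits (ANC4+) or skilled birth attendance (SBA) —
#' optionally scaled.  The default scaling factor of 1 (identity) is a
#' documented placeholder: the internal linkage coefficients used by full
#' LiST are not public.
#'
#' @param linked_value Measured coverage fraction of the linked indicator.
#' @param link Which linked indicator, `"SBA"` or `"ANC4plus"`.
#' @param factor Scaling factor in \[0, 1\].
#' @return Assigned coverage fraction.
#' @examples
#' proxy_coverage(0.71, "SBA")            # 0.71
#' proxy_coverage(0.80, "ANC4plus", 0.5)  # 0.40
#' @export
proxy_coverage <- function(linked_value, link = c("SBA", "ANC4plus"),
                           factor = 1.0) {
  link <- match.arg(link)
  assert_fraction(linked_value, "linked indicator value")
  assert_fraction(factor, "proxy scaling factor")
  linked_value * factor
}

#' Harmonize survey estimates into per-intervention anchors and rates
#'
#' For every unit-by-intervention pair: choose the reference (pre-baseline)
#' estimate by source preference ([select_reference()]), resolve apparent
#' declines against the 2010 baseline value ([resolve_decline()]), and derive
#' the pre-baseline annual rate of change.  Pairs with no reference estimate
#' at all fall back to a flat trend at the baseline value (same behaviour as
#' the conflict rule), with the fallback reference placed at 2006.
#'
#' @param surveys Survey-estimate data frame covering one or more units and
#'   interventions; must contain exactly one `BASELINE2010` row per pair.
#' @param prefer_source_order Passed to [select_reference()].
#' @return A data frame with one row per (unit, intervention):
#'   `unit_id`, `intervention_id`, `ref_year`, `ref_source`, `ref_coverage`,
#'   `base_coverage`, `rate` (fraction per year), `conflict`, `no_reference`.
#' @export
harmonize_surveys <- function(surveys,
                              prefer_source_order = c("MICS2006", "DHS2003")) {
  surveys <- validate_survey_estimates(as.data.frame(surveys))
  keys <- unique(surveys[, c("unit_id", "intervention_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    u <- keys$unit_id[i]; iv <- keys$intervention_id[i]
    grp <- surveys[surveys$unit_id == u & surveys$intervention_id == iv, ,
                   drop = FALSE]
    base <- grp[grp$source == "BASELINE2010", , drop = FALSE]
    if (nrow(base) != 1L) {
      stop(sprintf("unit '%s', intervention '%s': need exactly one baseline estimate, found %d",
                   u, iv, nrow(base)), call. = FALSE)
    }
    pre <- grp[grp$source != "BASELINE2010", , drop = FALSE]
    if (nrow(pre) == 0L) {
      # no reference data: conservative flat trend at the baseline value
      return(data.frame(
        unit_id = u, intervention_id = iv,
        ref_year = 2006L, ref_source = NA_character_,
        ref_coverage = base$coverage, base_coverage = base$coverage,
        rate = 0, conflict = FALSE, no_reference = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    ref <- select_reference(pre, prefer_source_order)
    anchors <- resolve_decline(c(ref$year, ref$coverage),
                               c(base$year, base$coverage))
    rate <- (anchors$coverage[2] - anchors$coverage[1]) /
      (anchors$year[2] - anchors$year[1])
    data.frame(
      unit_id = u, intervention_id = iv,
      ref_year = anchors$year[1], ref_source = ref$source,
      ref_coverage = anchors$coverage[1], base_coverage = anchors$coverage[2],
      rate = rate, conflict = attr(anchors, "conflict"), no_reference = FALSE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
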