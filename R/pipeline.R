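#' Run the full projection pipeline on a study
#'
#' Executes harmonize -> scenarios -> project -> decompose for every unit in
#' the study: harmonizes the survey anchors ([harmonize_surveys()]), builds
#' the fixed-coverage, scale-up, and secular-trend coverage trajectories
#' ([build_scenarios()]), computes each projection's percent reduction in
#' under-five mortality between the horizon endpoints
#' ([percent_reduction()]), and decomposes the scale-up reduction by
#' intervention in both isolation and simultaneous modes
#' ([decompose_by_intervention()]).
#'
#' @param study A `"listlite_study"` (from [burkina_fixture()],
#'   [generate_study()], or [read_run_config()]).
#' @param out_dir Optional directory; when given, the result tables are
#'   written as CSV and the manifest as JSON.
#' @param verbose Log harmonization events (conflict rule, missing
#'   references, rate substitutions) with [message()].
#' @return A list of class `"listlite_run"`:
#' \describe{
#'   \item{projections}{one row per (unit, scenario): `mortality_multiplier`,
#'     `percent_reduction`.}
#'   \item{table2_like}{per unit: scale-up R, secular-trend R, and their
#'     difference (the program-attributable reduction).}
#'   \item{table3_like}{per intervention on the pooled unit: baseline,
#'     target, gap (percent), and the isolation-mode percent reduction.}
#'   \item{decomposition}{per (unit, intervention): isolation and
#'     simultaneous per-intervention reductions under scale-up.}
#'   \item{scenario_coverage}{the long trajectory table.}
#'   \item{harmonized}{the harmonized anchor/rate table.}
#'   \item{manifest}{run provenance: package version, config hash, counts.}
#' }
#' @examples
#' run <- run_pipeline(burkina_fixture())
#' head(run$table2_like)
#' @export
run_pipeline <- function(study, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(study, "listlite_study"))
  if (!length(study$units)) stop("study has no units", call. = FALSE)
  harmonized <- harmonize_surveys(study$surveys)
  if (verbose) log_harmonization(harmonized, study$scenario)
  scen_cov <- build_scenarios(harmonized, study$scenario)
  h0 <- study$scenario$horizon[1]; h1 <- study$scenario$horizon[2]
  jobs <- enumerate_projections(study$units)

  proj_rows <- vector("list", nrow(jobs))
  decomp_rows <- list()
  for (j in seq_len(nrow(jobs))) {
    u <- jobs$unit_id[j]; sk <- jobs$scenario[j]
    hu <- harmonized[harmonized$unit_id == u, , drop = FALSE]
    baseline_cov <- stats::setNames(hu$base_coverage, hu$intervention_id)
    sc <- scen_cov[scen_cov$unit_id == u & scen_cov$scenario == sk &
                     scen_cov$year == h1, , drop = FALSE]
    scenario_cov <- stats::setNames(sc$coverage, sc$intervention_id)
    R <- percent_reduction(study$causes, baseline_cov, scenario_cov,
                           study$effectiveness)
    proj_rows[[j]] <- data.frame(
      unit_id = u, scenario = sk,
      mortality_multiplier = 1 - R / 100, percent_reduction = R,
      stringsAsFactors = FALSE)
    if (sk == "scale_up") {
      iso <- decompose_by_intervention(study$causes, baseline_cov,
                                       scenario_cov, study$effectiveness,
                                       mode = "isolation")
      sim <- decompose_by_intervention(study$causes, baseline_cov,
                                       scenario_cov, study$effectiveness,
                                       mode = "simultaneous")
      decomp_rows[[length(decomp_rows) + 1L]] <- data.frame(
        unit_id = u, intervention_id = names(iso),
        isolation_R = unname(iso), simultaneous_R = unname(sim[names(iso)]),
        stringsAsFactors = FALSE)
    }
  }
  projections <- do.call(rbind, proj_rows)
  rownames(projections) <- NULL
  decomposition <- do.call(rbind, decomp_rows)
  rownames(decomposition) <- NULL

  su <- projections[projections$scenario == "scale_up", ]
  se <- projections[projections$scenario == "secular_trend", ]
  table2 <- data.frame(
    unit_id = su$unit_id,
    scale_up_R = su$percent_reduction,
    secular_R = se$percent_reduction[match(su$unit_id, se$unit_id)],
    stringsAsFactors = FALSE)
  table2$difference <- attributable_reduction(table2$scale_up_R,
                                              table2$secular_R)

  pu <- study$pooled_unit
  hp <- harmonized[harmonized$unit_id == pu, , drop = FALSE]
  dp <- decomposition[decomposition$unit_id == pu, , drop = FALSE]
  targets <- study$scenario$targets
  table3 <- data.frame(
    intervention_id = hp$intervention_id,
    baseline_percent = 100 * hp$base_coverage,
    target_percent = 100 * unname(targets[hp$intervention_id]),
    stringsAsFactors = FALSE)
  # coverage change realized by the scale-up scenario (target minus
  # baseline for scaled interventions, continuation/cap otherwise)
  sc_end <- scen_cov[scen_cov$unit_id == pu &
                       scen_cov$scenario == "scale_up" &
                       scen_cov$year == h1, , drop = FALSE]
  table3$gap_percent <- 100 * sc_end$coverage[
    match(table3$intervention_id, sc_end$intervention_id)] -
    table3$baseline_percent
  table3$isolation_R <- dp$isolation_R[
    match(table3$intervention_id, dp$intervention_id)]

  manifest <- list(
    package = "listlite",
    version = as.character(utils::packageVersion("listlite")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    study = study$name,
    config_hash = study_hash(study),
    n_units = length(study$units),
    n_interventions = length(unique(harmonized$intervention_id)),
    n_projections = nrow(projections),
    horizon = study$scenario$horizon,
    cap_percent = 100 * study$scenario$cap
  )

  run <- structure(list(
    projections = projections, table2_like = table2, table3_like = table3,
    decomposition = decomposition, scenario_coverage = scen_cov,
    harmonized = harmonized, manifest = manifest
  ), class = "listlite_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.listlite_run <- function(x, ...) {
  cat("listlite run:", x$manifest$study, "\n")
  cat(sprintf("  %d projections (%d units x 3 scenarios)\n",
              x$manifest$n_projections, x$manifest$n_units))
  pooled <- x$table2_like[nrow(x$table2_like), ]
  cat(sprintf("  last unit (%s): scale-up %.1f%%, secular %.1f%%, attributable %.1f pp\n",
              pooled$unit_id, pooled$scale_up_R, pooled$secular_R,
              pooled$difference))
  invisible(x)
}

log_harmonization <- function(harmonized, spec) {
  for (i in seq_len(nrow(harmonized))) {
    h <- harmonized[i, ]
    if (isTRUE(h$conflict)) {
      message(sprintf("[harmonize] %s/%s: reference %.0f%% (%d) above baseline %.0f%%; flat trend applied",
                      h$unit_id, h$intervention_id, 100 * h$ref_coverage,
                      h$ref_year, 100 * h$base_coverage))
    }
    if (isTRUE(h$no_reference)) {
      message(sprintf("[harmonize] %s/%s: no pre-baseline reference; flat trend at baseline",
                      h$unit_id, h$intervention_id))
    }
  }
  for (r in names(spec$rate_substitutions)) {
    message(sprintf("[scenario] secular rate for %s substituted from %s",
                    r, spec$rate_substitutions[[r]]))
  }
}

# stable hash of the study inputs via canonical JSON -> md5
study_hash <- function(study) {
  canon <- list(
    surveys = study$surveys[order(study$surveys$unit_id,
                                  study$surveys$intervention_id,
                                  study$surveys$year), ],
    targets = as.list(study$scenario$targets),
    cap = study$scenario$cap,
    subs = as.list(study$scenario$rate_substitutions),
    horizon = study$scenario$horizon,
    effectiveness = study$effectiveness,
    causes = as.list(unclass(study$causes))
  )
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(canon, tf, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tf))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, quote = FALSE)
  w(run$projections, "projection_results.csv")
  w(run$table2_like, "table2_like.csv")
  w(run$table3_like, "table3_like.csv")
  w(run$decomposition, "attribution.csv")
  write_scenario_coverage(run$scenario_coverage,
                          file.path(out_dir, "scenario_coverage.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Sensitivity analysis: scale everything up to the cap
#'
#' Rebuilds the scale-up scenario with every program intervention's target
#' replaced by `cap`, except interventions whose original target already
#' equals or exceeds the cap (in the bundled study, vitamin A
#' supplementation, whose target is already 90%), which keep their original
#' targets.  Reports the joint percent reduction under the original targets
#' and under the cap-level targets for every unit.
#'
#' @param study A `"listlite_study"`.
#' @param cap Target coverage fraction applied to all program interventions.
#' @param keep_original Intervention ids that keep their original targets;
#'   defaults to those with original target >= `cap`.
#' @return Data frame: `unit_id`, `original_R`, `sensitivity_R`.
#' @export
sensitivity_all_to_cap <- function(study, cap = 0.90, keep_original = NULL) {
  stopifnot(inherits(study, "listlite_study"))
  assert_fraction(cap, "cap")
  if (cap == 0) stop("cap must be positive", call. = FALSE)
  targets <- study$scenario$targets
  if (is.null(keep_original)) {
    keep_original <- names(targets)[targets >= cap]
  }
  new_targets <- targets
  new_targets[setdiff(names(targets), keep_original)] <- cap
  alt <- study
  alt$scenario <- scenario_spec(
    targets = new_targets, cap = study$scenario$cap,
    rate_substitutions = study$scenario$rate_substitutions,
    horizon = study$scenario$horizon)
  orig_run <- run_pipeline(study)
  alt_run <- run_pipeline(alt)
  o <- orig_run$projections[orig_run$projections$scenario == "scale_up", ]
  a <- alt_run$projections[alt_run$projections$scenario == "scale_up", ]
  data.frame(
    unit_id = o$unit_id,
    original_R = o$percent_reduction,
    sensitivity_R = a$percent_reduction[match(o$unit_id, a$unit_id)],
    stringsAsFactors = FALSE)
}
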