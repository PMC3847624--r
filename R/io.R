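# Plain-CSV readers and writers.  All files carry coverage in percent
# (0-100), matching how survey reports print coverage; the engine works in
# fractions.

#' Read and write coverage-survey CSV files
#'
#' The survey file has columns `unit_id, intervention_id, year, source,
#' stratum, coverage_percent` (UTF-8, header required).
#'
#' @param path File path.
#' @return For the reader, a validated [survey_estimates()] frame (coverage
#'   as fractions).
#' @export
read_coverage_surveys <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("coverage_percent" %in% names(x))) {
    stop("survey file needs a 'coverage_percent' column", call. = FALSE)
  }
  x$coverage <- x$coverage_percent / 100
  x$coverage_percent <- NULL
  if (!("stratum" %in% names(x))) x$stratum <- "rural"
  validate_survey_estimates(x)
}

#' @rdname read_coverage_surveys
#' @param surveys A survey-estimates frame.
#' @export
write_coverage_surveys <- function(surveys, path) {
  surveys <- validate_survey_estimates(as.data.frame(surveys))
  out <- surveys[, c("unit_id", "intervention_id", "year", "source",
                     "stratum")]
  out$coverage_percent <- 100 * surveys$coverage
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intervention-effectiveness CSV
#'
#' Columns: `intervention_id, cause, effectiveness, affected_fraction`
#' (both fractions).
#'
#' @param path File path.
#' @return An [effectiveness_table()].
#' @export
read_effectiveness <- function(path) {
  effectiveness_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a cause-of-death structure CSV
#'
#' Columns: `cause, fraction_percent`.
#'
#' @param path File path.
#' @return A [cause_structure()].
#' @export
read_cause_structure <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cause_structure(stats::setNames(x$fraction_percent / 100, x$cause))
}

#' Read a target-coverage CSV
#'
#' Columns: `intervention_id, target_percent`.
#'
#' @param path File path.
#' @return Named numeric vector of target fractions.
#' @export
read_targets <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(x$target_percent / 100, x$intervention_id)
}

#' Read a skilled-birth-attendance provider breakdown and recompute coverage
#'
#' The file has one row per unit with provider-category columns (fractions
#' of births by attendant type); any columns other than `unit_id` and the
#' included categories are preserved unchanged.  Coverage is recomputed as
#' the sum over `included` categories (see [recompute_sba()]).
#'
#' @param path File path.
#' @param included Provider categories to count as skilled.
#' @return The input frame with a `coverage` column (fraction) appended.
#' @export
read_sba_breakdown <- function(path,
                               included = c("doctor", "nurse", "midwife")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  provider_cols <- intersect(
    c("doctor", "nurse", "midwife", "auxiliary_midwife", "matrone", "other"),
    names(x))
  x$coverage <- vapply(seq_len(nrow(x)), function(i) {
    recompute_sba(unlist(x[i, provider_cols, drop = TRUE]), included)
  }, numeric(1))
  x
}

#' Write the long scenario-coverage table
#'
#' Columns written: `unit_id, scenario, intervention_id, year,
#' coverage_percent`.
#'
#' @param scenarios Output of [build_scenarios()].
#' @param path File path.
#' @export
write_scenario_coverage <- function(scenarios, path) {
  out <- scenarios[, c("unit_id", "scenario", "intervention_id", "year")]
  out$coverage_percent <- 100 * scenarios$coverage
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration and assemble a study
#'
#' The configuration names the input files and scenario settings:
#' ```yaml
#' paths:
#'   surveys: coverage_surveys.csv
#'   targets: targets.csv
#'   effectiveness: effectiveness.csv
#'   causes: causes.csv
#' harmonization:
#'   prefer_source_order: [MICS2006, DHS2003]
#'   proxy_links:
#'     mgso4: {link: SBA, of: sba, factor: 1.0}
#' scenarios:
#'   cap_percent: 90
#'   rate_substitutions: {act_malaria: antibiotics_pneumonia}
#'   horizon: [2010, 2013]
#' ```
#' All referenced files must exist and parse before any computation starts.
#'
#' @param path Path to the YAML file.  Relative paths in `paths:` are
#'   resolved against the YAML file's directory.
#' @return A `"listlite_study"` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)
  needed <- c("surveys", "targets", "effectiveness", "causes")
  missing_keys <- setdiff(needed, names(cfg$paths))
  if (length(missing_keys)) {
    stop("config paths: missing ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  files <- vapply(cfg$paths[needed], resolve, character(1))
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    stop("config references missing file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  surveys <- read_coverage_surveys(files[["surveys"]])
  targets <- read_targets(files[["targets"]])
  eff <- read_effectiveness(files[["effectiveness"]])
  causes <- read_cause_structure(files[["causes"]])

  links <- cfg$harmonization$proxy_links
  if (!is.null(links)) surveys <- apply_proxy_links(surveys, links)

  sc <- cfg$scenarios
  scen <- scenario_spec(
    targets = targets,
    cap = if (is.null(sc$cap_percent)) 0.90 else sc$cap_percent / 100,
    rate_substitutions = sc$rate_substitutions,
    horizon = if (is.null(sc$horizon)) c(2010L, 2013L) else
      as.integer(sc$horizon)
  )
  units <- unique(surveys$unit_id)
  new_study(surveys = surveys, scenario = scen, effectiveness = eff,
            causes = causes, units = units,
            pooled_unit = if ("all_districts" %in% units) "all_districts"
            else units[1],
            name = paste("study from", basename(path)))
}

#' Derive survey rows for unmeasured interventions from linked indicators
#'
#' For each proxy link `new_id: {of: measured_id, link: "SBA"|"ANC4plus",
#' factor: f}`, every survey estimate of the measured indicator is copied to
#' the unmeasured intervention with coverage scaled by `factor` (see
#' [proxy_coverage()]).
#'
#' @param surveys A survey-estimates frame.
#' @param links Named list of links as above.
#' @return The augmented survey-estimates frame.
#' @export
apply_proxy_links <- function(surveys, links) {
  for (new_id in names(links)) {
    lk <- links[[new_id]]
    if (is.null(lk$of) || is.null(lk$link)) {
      stop("proxy link '", new_id, "' needs 'of' and 'link' fields",
           call. = FALSE)
    }
    src <- surveys[surveys$intervention_id == lk$of, , drop = FALSE]
    if (nrow(src) == 0L) {
      stop("proxy link '", new_id, "': linked indicator '", lk$of,
           "' has no survey estimates", call. = FALSE)
    }
    factor <- if (is.null(lk$factor)) 1.0 else lk$factor
    src$intervention_id <- new_id
    src$coverage <- proxy_coverage(src$coverage, lk$link, factor)
    surveys <- rbind(surveys, src)
  }
  validate_survey_estimates(surveys)
}
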