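#' The bundled Burkina Faso-style study
#'
#' A ready-to-run study assembled from the package's bundled fixtures:
#' published pooled (all-districts) 2010 baseline coverage and 2013 program
#' targets for twelve accelerated child-survival interventions, the
#' under-five cause-of-death structure (malaria 24%, pneumonia 18%, diarrhea
#' 12%, neonatal 22%, other 24%), and the 14-unit projection structure of
#' the evaluation: nine districts in two regions, the two regions pooled,
#' two intervention-group strata (community case management of pneumonia
#' implemented or not), and all districts together.
#'
#' Two fixture components are **synthetic stand-ins**, clearly labelled as
#' such in their filenames, because the originals are not public:
#' `burkina_reference_synthetic.csv` (national rural 2003/2006 reference
#' anchors; the vitamin A reference is set above its 2010 baseline so the
#' flat-trend conflict rule is exercised, and ACTs have no reference — their
#' secular rate is donor-substituted from oral antibiotics) and
#' `effectiveness_synthetic.csv` (a literature-style approximation, **not**
#' the LiST internal CHERG database; mortality results from this study are
#' therefore comparable to the published analysis in structure and ordering,
#' not numerically).
#'
#' District-level baseline variation around the pooled values is synthetic:
#' independent uniform offsets of at most `district_spread` drawn with a
#' fixed internal seed, so the fixture is reproducible.  The `all_districts`
#' unit carries the pooled values exactly.
#'
#' @param district_spread Half-width of the uniform district offsets applied
#'   to pooled baseline coverage (fraction, default 0.08).  Zero gives every
#'   unit the pooled values.
#' @return A `"listlite_study"` object (see [generate_study()]), without
#'   ground truth.
#' @examples
#' study <- burkina_fixture()
#' study
#' @export
burkina_fixture <- function(district_spread = 0.08) {
  assert_fraction(district_spread, "district_spread")
  ext <- function(f) system.file("extdata", f, package = "listlite",
                                 mustWork = TRUE)
  baseline <- utils::read.csv(ext("burkina_baseline.csv"),
                              stringsAsFactors = FALSE)
  targets_df <- utils::read.csv(ext("burkina_targets.csv"),
                                stringsAsFactors = FALSE)
  refs <- utils::read.csv(ext("burkina_reference_synthetic.csv"),
                          stringsAsFactors = FALSE)
  eff <- effectiveness_table(utils::read.csv(ext("effectiveness_synthetic.csv"),
                                             stringsAsFactors = FALSE))
  causes_df <- utils::read.csv(ext("burkina_causes.csv"),
                               stringsAsFactors = FALSE)
  causes <- cause_structure(stats::setNames(causes_df$fraction_percent / 100,
                                            causes_df$cause))

  districts <- c("barsalogho", "boulsa", "kaya", "kongoussi", "gourcy",
                 "ouahigouya", "seguenega", "yako", "titao")
  units <- c(districts, "center_north", "north",
             "pmnch_without_ccm", "pmnch_with_ccm", "all_districts")
  ivs <- baseline$intervention_id
  base_frac <- stats::setNames(baseline$baseline_percent / 100, ivs)

  surveys <- with_seed(20100613L, {
    rows <- lapply(units, function(u) {
      off <- if (u == "all_districts") rep(0, length(ivs)) else
        stats::runif(length(ivs), -district_spread, district_spread)
      vals <- pmin(pmax(base_frac + off, 0), 1)
      base_rows <- data.frame(
        unit_id = u, intervention_id = ivs, year = 2010L,
        source = "BASELINE2010", stratum = "rural", coverage = unname(vals),
        stringsAsFactors = FALSE)
      # national rural reference anchors are shared across all projections
      ref_rows <- data.frame(
        unit_id = u, intervention_id = refs$intervention_id,
        year = refs$year, source = refs$source, stratum = "rural",
        coverage = refs$coverage_percent / 100, stringsAsFactors = FALSE)
      rbind(ref_rows, base_rows)
    })
    validate_survey_estimates(do.call(rbind, rows))
  })

  scen <- scenario_spec(
    targets = stats::setNames(targets_df$target_percent / 100,
                              targets_df$intervention_id),
    cap = 0.90,
    rate_substitutions = c(act_malaria = "antibiotics_pneumonia"),
    horizon = c(2010L, 2013L)
  )
  new_study(surveys = surveys, scenario = scen, effectiveness = eff,
            causes = causes, units = units, pooled_unit = "all_districts",
            name = "Burkina Faso-style acceleration study (bundled fixture)",
            u5mr_2010 = 184)
}
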