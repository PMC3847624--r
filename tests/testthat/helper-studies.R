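# Shared builders for small engine inputs used across test files.

# one intervention, one cause, potency E*A = 0.5
unit_eff <- function() {
  data.frame(intervention_id = "tx", cause = "malaria",
             effectiveness = 1, affected_fraction = 0.5,
             stringsAsFactors = FALSE)
}

# a small random engine configuration: causes, effectiveness entries, and
# baseline/scenario coverage.  Draws from the *current* RNG stream so
# callers control seeding.
random_engine_config <- function(n_interventions = 3L, n_causes = 3L) {
  cz <- paste0("cause", seq_len(n_causes))
  f <- runif(n_causes, 0.1, 1)
  f <- 0.9 * f / sum(f)  # leave >= 10% for the 'other' residual
  causes <- cause_structure(setNames(f, cz))
  ivs <- paste0("iv", seq_len(n_interventions))
  entries <- do.call(rbind, lapply(ivs, function(iv) {
    on <- sample(cz, sample(1:n_causes, 1))
    data.frame(intervention_id = iv, cause = on,
               effectiveness = runif(length(on), 0.3, 0.9),
               affected_fraction = runif(length(on), 0.4, 0.95),
               stringsAsFactors = FALSE)
  }))
  baseline <- setNames(runif(n_interventions, 0.05, 0.5), ivs)
  scenario <- pmin(baseline + runif(n_interventions, 0.05, 0.4), 0.95)
  list(causes = causes, effectiveness = effectiveness_table(entries),
       baseline = baseline, scenario = setNames(scenario, ivs))
}

# survey frame for one unit with a MICS reference and 2010 baseline
two_anchor_surveys <- function(unit = "u1", iv = "tx",
                               ref = c(2006, 0.20), base = 0.40) {
  survey_estimates(
    unit_id = unit, intervention_id = iv,
    year = c(ref[1], 2010), source = c("MICS2006", "BASELINE2010"),
    coverage = c(ref[2], base))
}
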