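#' Micro-simulation oracle for the analytic mortality engine
#'
#' An independent Monte-Carlo check of [percent_reduction()].  For each arm
#' (baseline and scenario coverage), `n_children` children at risk of dying
#' are simulated: each is assigned a potential cause of death with
#' probability equal to the cause fraction; for every intervention with an
#' effectiveness entry on that cause, receipt is drawn as an independent
#' Bernoulli event at the arm's coverage, and a received intervention averts
#' the death with probability effectiveness x affected fraction,
#' independently across interventions.  The child dies only if no received
#' intervention averts the death.
#'
#' Because the cause fractions describe the distribution of *deaths* at
#' baseline, the estimator mixes per-cause death-rate *ratios*:
#' \deqn{\hat R = 100 (1 - \sum_c f_c \, \hat q_c^{scen} / \hat q_c^{base}),}
#' which converges to the analytic percent reduction as `n_children` grows.
#' The Monte-Carlo standard error is computed by the delta method from the
#' per-cause binomial variances.
#'
#' @inheritParams percent_reduction
#' @param n_children Number of simulated children per arm.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A list with `estimate` (percent reduction), `se` (Monte-Carlo
#'   standard error), and `n_children`.
#' @examples
#' eff <- data.frame(intervention_id = "tx", cause = "malaria",
#'                   effectiveness = 1, affected_fraction = 0.5)
#' microsim_oracle(cause_structure(c(malaria = 1)),
#'                 c(tx = 0.2), c(tx = 0.6), eff,
#'                 n_children = 1e4, seed = 1)
#' @export
microsim_oracle <- function(causes, baseline_cov, scenario_cov,
                            effectiveness, n_children, seed) {
  stopifnot(n_children >= 1)
  causes <- cause_structure(unclass(causes))
  effectiveness <- effectiveness_table(effectiveness)
  cz_names <- names(causes)

  simulate_arm <- function(coverage) {
    assigned <- sample(cz_names, n_children, replace = TRUE,
                       prob = as.numeric(causes))
    q <- stats::setNames(rep(1, length(cz_names)), cz_names)
    n_c <- stats::setNames(integer(length(cz_names)), cz_names)
    for (cz in cz_names) {
      nc <- sum(assigned == cz)
      n_c[cz] <- nc
      if (nc == 0L) next
      entries <- effectiveness[effectiveness$cause == cz &
                                 effectiveness$intervention_id %in%
                                 names(coverage), , drop = FALSE]
      if (nrow(entries) == 0L) { q[cz] <- 1; next }  # deterministic death
      dies <- rep(TRUE, nc)
      for (i in seq_len(nrow(entries))) {
        received <- stats::runif(nc) < coverage[[entries$intervention_id[i]]]
        averted <- received & (stats::runif(nc) < entries$potency[i])
        dies <- dies & !averted
      }
      q[cz] <- mean(dies)
    }
    list(q = q, n = n_c)
  }

  with_seed(seed, {
    base <- simulate_arm(baseline_cov)
    scen <- simulate_arm(scenario_cov)

    ratio <- stats::setNames(rep(1, length(cz_names)), cz_names)
    var_ratio <- stats::setNames(rep(0, length(cz_names)), cz_names)
    for (cz in cz_names) {
      touched <- any(effectiveness$cause == cz &
                       effectiveness$intervention_id %in% names(baseline_cov))
      if (!touched) next  # q = 1 in both arms by construction, ratio exactly 1
      if (base$n[cz] == 0L || scen$n[cz] == 0L || base$q[cz] == 0) {
        # cause unobserved at this n; its multiplier defaults to 1
        next
      }
      qb <- base$q[cz]; qs <- scen$q[cz]
      ratio[cz] <- qs / qb
      v_qs <- qs * (1 - qs) / scen$n[cz]
      v_qb <- qb * (1 - qb) / base$n[cz]
      var_ratio[cz] <- v_qs / qb^2 + qs^2 * v_qb / qb^4
    }
    f <- as.numeric(causes)
    list(
      estimate = 100 * (1 - sum(f * ratio)),
      se = 100 * sqrt(sum(f^2 * var_ratio)),
      n_children = n_children
    )
  })
}
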