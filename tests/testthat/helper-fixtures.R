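# Shared fixtures, built in code and cached per test session.

fixture_env <- new.env(parent = emptyenv())

# A mid-sized default cohort reused across tests that only read it.
shared_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    cfg <- dgp_config(n_mothers = 2000L, n_villages = 80L, seed = 1234L)
    fixture_env$cohort <- generate_cohort(cfg, compute_truth = FALSE)
  }
  fixture_env$cohort
}

# Analysis-ready table for the shared cohort (aggregate exposure attached,
# restricted to the >=1-visit subsample with the >=4 binary outcome).
shared_ge4_table <- function() {
  if (is.null(fixture_env$ge4)) {
    co <- shared_cohort()
    prep <- prepare_analysis_table(co$records)
    tab <- prep$table
    spec <- outcome_spec("ge4_vs_1to3")
    d <- tab[spec$subsample(tab$anc_visits), , drop = FALSE]
    d$.y <- spec$outcome(d$anc_visits)
    fixture_env$ge4 <- list(data = d, covariate_cols = prep$covariate_cols)
  }
  fixture_env$ge4
}

# Fitted nuisance + targeted means on the shared ge4 table (glm library).
shared_tmle <- function() {
  if (is.null(fixture_env$tmle)) {
    f <- shared_ge4_table()
    nuis <- fit_nuisance(f$data, ".y", "cat_aggregate", f$covariate_cols,
                         library = learner_library("glm"), n_folds = 5,
                         seed = 99L, cv = FALSE)
    means <- tmle_counterfactual_means(f$data$.y, f$data$cat_aggregate,
                                       nuis, "binary")
    fixture_env$tmle <- list(nuisance = nuis, means = means,
                             data = f$data, covariate_cols = f$covariate_cols)
  }
  fixture_env$tmle
}

# 12-row discrete toy with hand-computable stratum means (one binary
# covariate, all exposure levels present in both strata).
toy12 <- function() {
  data.frame(
    village_id = rep(1:4, 3),
    w = rep(c(0, 1), each = 6),
    a = factor(rep(c("low", "medium", "high"), 4),
               levels = c("low", "medium", "high")),
    y = c(0, 1, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1)
  )
}
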