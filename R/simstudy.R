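# Monte-Carlo validation harness: parameter recovery, double robustness,
# CI coverage, and oracle equivalence on a discrete toy fixture.

#' Summarize replicated estimates against a known truth
#'
#' @param estimates per-replicate point estimates.
#' @param truth true parameter value.
#' @param ses per-replicate standard errors (optional).
#' @param covered per-replicate CI coverage indicators (optional).
#' @param estimator,n labels.
#' @return object of class `experiment_result` with `bias`, `sd`
#'   (population SD across replicates), `mean_se`, `rmse`
#'   (`rmse^2 = bias^2 + sd^2` exactly), `coverage`, `estimates`.
#' @export
experiment_result <- function(estimates, truth, ses = NULL, covered = NULL,
                              estimator = "tmle", n = NA_integer_) {
  bias <- mean(estimates) - truth
  sd_pop <- sqrt(mean((estimates - mean(estimates))^2))
  out <- list(
    estimator = estimator, n = n, replicates = length(estimates),
    truth = truth, bias = bias, sd = sd_pop,
    mean_se = if (is.null(ses)) NA_real_ else mean(ses),
    rmse = sqrt(mean((estimates - truth)^2)),
    coverage = if (is.null(covered)) NA_real_ else mean(covered),
    estimates = estimates
  )
  class(out) <- "experiment_result"
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d, %d reps): truth %.4f, bias %.4f, SD %.4f, mean SE %.4f, RMSE %.4f, coverage %s\n",
    x$estimator, x$n, x$replicates, x$truth, x$bias, x$sd, x$mean_se, x$rmse,
    if (is.na(x$coverage)) "NA" else sprintf("%.3f", x$coverage)))
  invisible(x)
}

derive_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

# Generate one replicate cohort and produce the analysis pieces needed for
# a single-index TMLE/G-computation run: imputed table with the aggregate
# exposure category attached, restricted to the outcome spec's subsample.
replicate_table <- function(cfg, spec) {
  cohort <- inject_missingness(generate_cohort(cfg, compute_truth = FALSE))
  imp <- impute_median_with_indicators(cohort$records, dgp_covariate_names())
  tab <- imp$table
  tab$cat_aggregate <-
    categorize_quantile(score_weai(tab[, cfg$item_schema$item],
                                   cfg$item_schema)$aggregate)$category
  mask <- spec$subsample(tab$anc_visits)
  d <- tab[mask, , drop = FALSE]
  d$.y <- spec$outcome(d$anc_visits)
  d
}

#' Parameter-recovery experiment
#'
#' Replicated generate-and-analyze cycles against the generator's true
#' effect: each replicate draws a fresh cohort, derives the aggregate
#' empowerment category, estimates the requested pairwise effect, and the
#' summary reports bias, spread, RMSE and 95% CI coverage relative to the
#' Monte-Carlo truth.
#'
#' @param config a [dgp_config()]; `n_mothers` is overridden by `n`.
#' @param estimator `"tmle"` or `"gcomp"`.
#' @param n cohort size per replicate.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @param comparison,outcome effect to recover.
#' @param learners fast learner library used within each replicate.
#' @param n_folds Super Learner folds (ignored for a single learner, which
#'   skips cross-validation).
#' @param truth optionally precomputed true effect; otherwise computed once
#'   via [true_ate()] at `n_mc` draws.
#' @param n_mc Monte-Carlo size for the truth.
#' @return an `experiment_result`.
#' @export
run_recovery <- function(config, estimator = c("tmle", "gcomp"), n = 2000L,
                         n_reps = 300L, seed = 1L,
                         comparison = c("high", "low"),
                         outcome = "ge4_vs_1to3",
                         learners = "glm", n_folds = 5, truth = NULL,
                         n_mc = 1e6) {
  estimator <- match.arg(estimator)
  spec <- outcome_spec(outcome)
  kind <- if (outcome == "count") "count" else "binary"
  if (is.null(truth)) truth <- true_ate(config, comparison, outcome, n_mc)
  lib <- learner_library(learners)
  seeds <- derive_seeds(seed, n_reps)
  est <- se <- cov <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$n_mothers <- as.integer(n)
    cfg$seed <- seeds[r]
    d <- replicate_table(cfg, spec)
    covs <- c(dgp_covariate_names(),
              grep("_imputed$", names(d), value = TRUE))
    covs <- covs[vapply(covs, function(nm) stats::sd(d[[nm]]) > 0, logical(1))]
    if (estimator == "tmle") {
      nuis <- fit_nuisance(d, ".y", "cat_aggregate", covs, library = lib,
                           loss = if (kind == "binary") "nll" else "mse",
                           n_folds = n_folds, seed = seeds[r],
                           cv = length(lib) > 1L)
      means <- tmle_counterfactual_means(d$.y, d$cat_aggregate, nuis, kind)
      a <- tmle_ate(means, comparison, d$village_id)
    } else {
      a <- gcomp_ate(d, ".y", "cat_aggregate", covs, comparison,
                     outcome_kind = kind, n_boot = 100L, seed = seeds[r])
    }
    est[r] <- a$psi
    se[r] <- a$se
    cov[r] <- as.numeric(a$ci_lower <= truth && truth <= a$ci_upper)
  }
  experiment_result(est, truth, se, cov, estimator = estimator, n = n)
}

#' A data-generating process constructed to demonstrate double robustness
#'
#' A variant of the default configuration in which maternal education is a
#' deliberately dominant confounder: it carries most of the weight on the
#' latent empowerment construct and a large coefficient on the log visit
#' count, so omitting it from a nuisance model produces a clearly biased
#' plug-in while the doubly robust update recovers the truth.
#'
#' @param ... overrides passed to [dgp_config()].
#' @return a `dgp_config`.
#' @export
dgp_config_dr <- function(...) {
  dgp_config(
    confounding_coefficients = c(
      age = 0.10, cesd = -0.05, edu = 0.45, edu_diff = 0.05,
      hh_members = -0.05, children_u15 = -0.05, child_age = 0.02,
      wealth = 0.05
    ),
    outcome_coefficients = c(
      age = 0.03, cesd = -0.03, edu = 0.28, edu_diff = 0.02,
      hh_members = -0.02, children_u15 = -0.03, child_age = 0.00,
      wealth = 0.04
    ),
    village_sd = 0.1,
    ...
  )
}

strongest_confounder <- function(config) {
  shared <- intersect(names(config$confounding_coefficients),
                      names(config$outcome_coefficients))
  prod <- abs(config$confounding_coefficients[shared] *
                config$outcome_coefficients[shared])
  names(which.max(prod))
}

#' Double-robustness experiment
#'
#' Replicated comparison of TMLE against the naive plug-in (the mean
#' difference of the initial, untargeted outcome-regression predictions)
#' under a chosen misspecification pattern. Misspecification omits the
#' generator's strongest confounder from the corresponding nuisance model.
#'
#' @inheritParams run_recovery
#' @param which_misspecified one of `"outcome"`, `"propensity"`, `"both"`,
#'   `"neither"`.
#' @return list of class `dr_result` with `experiment_result`s `tmle` and
#'   `plugin`, plus `omitted` (the confounder dropped).
#' @export
run_double_robustness <- function(config = dgp_config_dr(),
                                  which_misspecified = c("outcome", "propensity",
                                                         "both", "neither"),
                                  n = 5000L, n_reps = 200L, seed = 1L,
                                  comparison = c("high", "low"),
                                  outcome = "ge4_vs_1to3",
                                  learners = "glm", truth = NULL, n_mc = 1e6) {
  which_misspecified <- match.arg(which_misspecified)
  spec <- outcome_spec(outcome)
  kind <- if (outcome == "count") "count" else "binary"
  if (is.null(truth)) truth <- true_ate(config, comparison, outcome, n_mc)
  lib <- learner_library(learners)
  omit <- strongest_confounder(config)
  seeds <- derive_seeds(seed, n_reps)
  est_t <- se_t <- cov_t <- est_p <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$n_mothers <- as.integer(n)
    cfg$seed <- seeds[r]
    d <- replicate_table(cfg, spec)
    covs_full <- c(dgp_covariate_names(),
                   grep("_imputed$", names(d), value = TRUE))
    covs_full <- covs_full[vapply(covs_full, function(nm) stats::sd(d[[nm]]) > 0,
                                  logical(1))]
    covs_q <- if (which_misspecified %in% c("outcome", "both")) {
      setdiff(covs_full, omit)
    } else covs_full
    covs_g <- if (which_misspecified %in% c("propensity", "both")) {
      setdiff(covs_full, omit)
    } else covs_full
    qr <- fit_outcome_regression(d, ".y", "cat_aggregate", covs_q, lib,
                                 loss = if (kind == "binary") "nll" else "mse",
                                 n_folds = 5, seed = seeds[r],
                                 cv = length(lib) > 1L)
    pr <- fit_propensity(d, "cat_aggregate", covs_g, lib, n_folds = 5,
                         seed = seeds[r] + 1L, cv = length(lib) > 1L)
    gb <- bound_propensity(pr$g)
    nuis <- new_nuisance(qr$qbar, gb$g, qbar_obs = qr$qbar_obs,
                         truncation_frac = gb$truncation_frac)
    means <- tmle_counterfactual_means(d$.y, d$cat_aggregate, nuis, kind)
    a <- tmle_ate(means, comparison, d$village_id)
    est_t[r] <- a$psi
    se_t[r] <- a$se
    cov_t[r] <- as.numeric(a$ci_lower <= truth && truth <= a$ci_upper)
    est_p[r] <- mean(qr$qbar[, comparison[1]]) - mean(qr$qbar[, comparison[2]])
  }
  out <- list(
    tmle = experiment_result(est_t, truth, se_t, cov_t, "tmle", n),
    plugin = experiment_result(est_p, truth, estimator = "plugin", n = n),
    omitted = omit, which_misspecified = which_misspecified
  )
  class(out) <- "dr_result"
  out
}

#' The discrete toy cohort used as a standardization oracle
#'
#' An 18-row cohort with one binary covariate `w`, all three exposure
#' levels in both covariate strata (three records per cell), a binary
#' outcome and singleton-free village ids. Shipped with hand-computed
#' nonparametrically standardized counterfactual means
#' (`sum_w Phat(w) * mean(y | a, w)`): 1/3, 1/2 and 2/3 for low, medium
#' and high.
#'
#' @return list with `data` (data.frame) and `hand_psi` (named length 3).
#' @export
toy_fixture <- function() {
  path <- system.file("extdata", "toy_cohort.csv", package = "ancempower")
  d <- utils::read.csv(path)
  d$a <- factor(d$a, levels = exposure_levels())
  truth <- jsonlite::read_json(
    system.file("extdata", "toy_cohort_truth.json", package = "ancempower"),
    simplifyVector = TRUE
  )
  list(data = d, hand_psi = unlist(truth$hand_psi))
}

# Brute-force nonparametric standardization: sum_w Phat(W=w) mean(Y|A=a,W=w).
hand_standardize <- function(data) {
  pw <- prop.table(table(data$w))
  vapply(exposure_levels(), function(lev) {
    sum(vapply(names(pw), function(w) {
      cell <- data$y[data$a == lev & data$w == as.numeric(w)]
      pw[[w]] * mean(cell)
    }, numeric(1)))
  }, numeric(1))
}

#' Saturated-model equivalence check
#'
#' On a discrete toy cohort with saturated nuisance models (exact stratum
#' means and empirical propensities), TMLE, parametric G-computation with a
#' saturated outcome model, and hand-computed nonparametric standardization
#' must agree. Returns the maximum absolute discrepancy over the three
#' pairwise comparisons.
#'
#' @param fixture list with `data` as returned by [toy_fixture()]; any
#'   data.frame with columns `y`, `a`, `w`, `village_id` works.
#' @return list with `max_discrepancy`, and the per-method pairwise effects.
#' @export
check_saturated_equivalence <- function(fixture = toy_fixture()) {
  d <- fixture$data
  nuis <- saturated_nuisance(d, "y", "a", "w")
  means <- tmle_counterfactual_means(d$y, d$a, nuis, "binary")
  hand <- hand_standardize(d)
  gc_means <- gcomp_ate(d, "y", "a", "w", c("high", "low"),
                        outcome_kind = "binary", cluster_col = "village_id",
                        formula = y ~ a * w, n_boot = 0)$level_means
  cmp <- canonical_comparisons()
  diff3 <- function(m) vapply(cmp, function(cc) m[cc[1]] - m[cc[2]], numeric(1))
  tmle_d <- diff3(means$psi); gc_d <- diff3(gc_means); hand_d <- diff3(hand)
  list(
    max_discrepancy = max(abs(tmle_d - gc_d), abs(tmle_d - hand_d)),
    tmle = tmle_d, gcomp = gc_d, hand = hand_d
  )
}
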