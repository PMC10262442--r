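#' Configuration for the synthetic survey cohort generator
#'
#' Defines the data-generating process for a clustered household survey of
#' mothers: covariates with configurable marginals, a latent empowerment
#' construct driven by those covariates (confounding), 15 ordinal
#' empowerment items produced by an ordinal-threshold model on the latent
#' value, and an antenatal-care visit count drawn from a zero-inflated
#' Poisson whose log-mean includes covariates, a shared village random
#' effect and additive effects of the observed empowerment category.
#'
#' Covariate marginal defaults match the study population the generator
#' emulates: age 25.8 (SD 5.5) years, CESD depressive score 13.8 (8.9),
#' education 6.6 (3.5) years, spousal education differential 1.1 (3.8),
#' household members 5.2 (1.9), children under 15 1.9 (0.8), child age
#' 13.5 (5.3) months. The outcome intercept and zero-inflation mass are
#' calibrated so the default cohort has mean ANC visits near 3.1 with about
#' 14% zero-visit mothers; `effect_high` is calibrated so the true
#' high-vs-low contrast on P(>= 4 visits | >= 1 visit) is 0.15.
#'
#' @param n_mothers,n_villages cohort size and number of village clusters.
#' @param seed integer RNG seed (default 2019).
#' @param covariate_marginals named list of `c(mean, sd)` pairs for the
#'   seven continuous covariates.
#' @param item_schema an [item_schema()].
#' @param confounding_coefficients named weights of standardized covariates
#'   (plus `wealth`) on the latent empowerment construct.
#' @param outcome_coefficients named weights of standardized covariates on
#'   the log-mean visit count.
#' @param intercept log-mean intercept of the Poisson component.
#' @param effect_medium,effect_high additive log-mean effects of medium/high
#'   empowerment category versus low.
#' @param zero_inflation probability of a structural zero-visit mother.
#' @param village_sd SD of the village random effect on the log-mean.
#' @param item_noise_sd SD of the item-specific noise added to the latent
#'   value before thresholding.
#' @param missing_rates named per-covariate MCAR missingness probabilities.
#' @return list of class `dgp_config`.
#' @export
dgp_config <- function(n_mothers = 1609L,
                       n_villages = 109L,
                       seed = 2019L,
                       covariate_marginals = list(
                         age = c(25.8, 5.5),
                         cesd = c(13.8, 8.9),
                         edu = c(6.6, 3.5),
                         edu_diff = c(1.1, 3.8),
                         hh_members = c(5.2, 1.9),
                         children_u15 = c(1.9, 0.8),
                         child_age = c(13.5, 5.3)
                       ),
                       item_schema = ancempower::item_schema(),
                       confounding_coefficients = c(
                         age = 0.30, cesd = -0.25, edu = 0.25, edu_diff = 0.10,
                         hh_members = -0.20, children_u15 = -0.10,
                         child_age = 0.05, wealth = 0.10
                       ),
                       outcome_coefficients = c(
                         age = 0.06, cesd = -0.06, edu = 0.10, edu_diff = 0.03,
                         hh_members = -0.04, children_u15 = -0.06,
                         child_age = 0.00, wealth = 0.08
                       ),
                       intercept = 1.0726,
                       effect_medium = 0.0956,
                       effect_high = 0.2318,
                       zero_inflation = 0.0962,
                       village_sd = 0.2,
                       item_noise_sd = 1.2,
                       missing_rates = c(edu_diff = 17 / 1609, cesd = 1 / 1609)) {
  cfg <- list(
    n_mothers = as.integer(n_mothers), n_villages = as.integer(n_villages),
    seed = as.integer(seed), covariate_marginals = covariate_marginals,
    item_schema = item_schema,
    confounding_coefficients = confounding_coefficients,
    outcome_coefficients = outcome_coefficients,
    intercept = intercept, effect_medium = effect_medium,
    effect_high = effect_high, zero_inflation = zero_inflation,
    village_sd = village_sd, item_noise_sd = item_noise_sd,
    missing_rates = missing_rates
  )
  validate_dgp_config(cfg)
  class(cfg) <- "dgp_config"
  cfg
}

validate_dgp_config <- function(cfg) {
  if (cfg$n_mothers <= 0L || cfg$n_villages <= 0L) {
    stop("n_mothers and n_villages must be positive")
  }
  if (cfg$n_villages > cfg$n_mothers) stop("n_villages must not exceed n_mothers")
  sds <- vapply(cfg$covariate_marginals, function(m) m[2], numeric(1))
  if (any(sds < 0)) stop("covariate SDs must be nonnegative")
  if (cfg$village_sd < 0 || cfg$item_noise_sd < 0) {
    stop("village_sd and item_noise_sd must be nonnegative")
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1) {
    stop("zero_inflation must lie in [0, 1)")
  }
  if (any(cfg$missing_rates < 0) || any(cfg$missing_rates > 1)) {
    stop("missing rates must lie in [0, 1]")
  }
  invisible(cfg)
}

# Names of the adjustment covariates in generated records, in model order.
dgp_covariate_names <- function() {
  c("age", "cesd", "edu", "edu_diff", "hh_members", "children_u15",
    "child_age", "wealth")
}

exposure_levels <- function() c("low", "medium", "high")

# Draw the raw structural quantities (covariates, village effects, latent
# empowerment, items, observed exposure category and outcome) for n mothers.
# Returns everything needed both for records and for analytic counterfactual
# means (linear predictor excluding the exposure effect).
simulate_raw <- function(cfg, n, seed) {
  set.seed(seed)
  m <- cfg$covariate_marginals
  draw <- function(name) stats::rnorm(n, m[[name]][1], m[[name]][2])
  age <- pmax(15, draw("age"))
  cesd <- round(pmin(60, pmax(0, draw("cesd"))))
  edu <- round(pmin(16, pmax(0, draw("edu"))))
  edu_diff <- round(draw("edu_diff"))
  hh_members <- pmax(2, round(draw("hh_members")))
  children_u15 <- pmax(0, round(draw("children_u15")))
  child_age <- round(pmin(24, pmax(6, draw("child_age"))))
  n_inlaws <- pmax(0, round(stats::rnorm(n, 1.3, 1.9)))

  # household wealth: latent gradient drives assets, sanitation and income
  z_wealth <- stats::rnorm(n)
  asset_alphas <- c(1.8, 1.2, 0.6, 0.2, -0.2, -0.6, -1.2, -1.8)
  assets <- vapply(asset_alphas, function(a) {
    stats::rbinom(n, 1L, stats::plogis(a + 1.5 * z_wealth))
  }, integer(n))
  colnames(assets) <- paste0("asset_", 1:8)
  water <- rep(1L, n)
  sanitation <- stats::rbinom(n, 1L, stats::plogis(0.78 + 0.8 * z_wealth))
  income <- exp(stats::rnorm(n, log(130), 0.8))

  covs <- data.frame(age = age, cesd = cesd, edu = edu, edu_diff = edu_diff,
                     hh_members = hh_members, children_u15 = children_u15,
                     child_age = child_age, wealth = z_wealth)
  # standardize on the configured marginal scale (wealth is already N(0,1))
  std <- covs
  for (nm in names(m)) std[[nm]] <- (covs[[nm]] - m[[nm]][1]) / max(m[[nm]][2], 1e-12)

  cc <- cfg$confounding_coefficients
  latent <- as.matrix(std[, names(cc), drop = FALSE]) %*% cc + stats::rnorm(n)
  latent <- as.numeric(latent)

  # ordinal-threshold items: latent + item noise cut at equally spaced
  # thresholds spanning [-1.3, 1.3] on the combined latent scale
  schema <- cfg$item_schema
  items <- matrix(0L, n, 15L, dimnames = list(NULL, schema$item))
  for (j in seq_len(15L)) {
    k <- schema$n_levels[j]
    thr <- seq(-1.3, 1.3, length.out = k + 1L)[2:k]
    lat_j <- latent + stats::rnorm(n, 0, cfg$item_noise_sd)
    items[, j] <- as.integer(rowSums(outer(lat_j, thr, ">=")))
  }

  emp_score <- score_weai(items, schema)$aggregate
  a_obs <- categorize_quantile(emp_score)$category

  village_id <- sample.int(cfg$n_villages, n, replace = TRUE)
  b_village <- stats::rnorm(cfg$n_villages, 0, cfg$village_sd)

  bc <- cfg$outcome_coefficients
  lp0 <- cfg$intercept +
    as.numeric(as.matrix(std[, names(bc), drop = FALSE]) %*% bc) +
    b_village[village_id]
  effect <- c(low = 0, medium = cfg$effect_medium, high = cfg$effect_high)
  mu_obs <- exp(lp0 + effect[as.character(a_obs)])
  structural_zero <- stats::rbinom(n, 1L, cfg$zero_inflation)
  anc <- ifelse(structural_zero == 1L, 0L, stats::rpois(n, mu_obs))

  list(covs = covs, items = items, emp_score = emp_score, a_obs = a_obs,
       village_id = village_id, latent = latent, lp0 = lp0, anc = anc,
       water = water, sanitation = sanitation, assets = assets,
       income = income, n_inlaws = n_inlaws)
}

#' Outcome specifications for the ANC analyses
#'
#' The four outcome specifications: the visit count on the full sample, and
#' the three pairwise binary contrasts of the categorical ANC measure, each
#' with its implied analysis subsample (>=4 vs 1-3 among mothers with >= 1
#' visit; none vs 1-3 among mothers with <= 3 visits; >=4 vs none among
#' mothers with 0 or >= 4 visits).
#'
#' @param kind one of `"count"`, `"ge4_vs_1to3"`, `"none_vs_1to3"`,
#'   `"ge4_vs_none"`.
#' @return list of class `outcome_spec` with `kind`, `label`, and functions
#'   `subsample(visits)` (logical mask) and `outcome(visits)` (binary or
#'   count outcome on the subsample scale).
#' @export
outcome_spec <- function(kind = c("count", "ge4_vs_1to3", "none_vs_1to3",
                                  "ge4_vs_none")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    count = list(
      label = "number of ANC visits",
      subsample = function(v) rep(TRUE, length(v)),
      outcome = function(v) as.numeric(v)
    ),
    ge4_vs_1to3 = list(
      label = "P(>=4 visits) among mothers with >=1 visit",
      subsample = function(v) v >= 1,
      outcome = function(v) as.numeric(v >= 4)
    ),
    none_vs_1to3 = list(
      label = "P(no ANC) among mothers with <=3 visits",
      subsample = function(v) v <= 3,
      outcome = function(v) as.numeric(v == 0)
    ),
    ge4_vs_none = list(
      label = "P(>=4 visits) among mothers with 0 or >=4 visits",
      subsample = function(v) v == 0 | v >= 4,
      outcome = function(v) as.numeric(v >= 4)
    )
  )
  out <- c(list(kind = kind), spec)
  class(out) <- "outcome_spec"
  out
}

outcome_spec_kinds <- function() {
  c("count", "ge4_vs_1to3", "none_vs_1to3", "ge4_vs_none")
}

# Analytic conditional counterfactual mean for one mother given the
# no-exposure linear predictor lp0, under exposure forced to level a.
# For the count spec this is E[Y(a)]; for binary specs it is the
# conditional probability of the "top" outcome given membership in the
# pair-defining visit set, computed from the zero-inflated Poisson law.
counterfactual_mean <- function(lp0, effect_a, pi0, kind) {
  mu <- exp(lp0 + effect_a)
  p_ge4 <- stats::ppois(3, mu, lower.tail = FALSE)
  p_zero <- pi0 + (1 - pi0) * exp(-mu)
  switch(kind,
    count = (1 - pi0) * mu,
    ge4_vs_1to3 = p_ge4 / (1 - exp(-mu)),
    none_vs_1to3 = p_zero / (pi0 + (1 - pi0) * stats::ppois(3, mu)),
    ge4_vs_none = (1 - pi0) * p_ge4 / (p_zero + (1 - pi0) * p_ge4)
  )
}

# Monte-Carlo truth: counterfactual means per exposure level and outcome
# spec. Covariates and village effects are drawn observationally at size
# n_mc; per-mother conditional means under each forced level are computed
# analytically from the structural model and averaged over the outcome
# spec's observed-data subsample.
true_counterfactual_means <- function(cfg, n_mc = 1e5, seed_offset = 777L) {
  raw <- simulate_raw(cfg, as.integer(n_mc),
                      (cfg$seed + seed_offset) %% .Machine$integer.max)
  effect <- c(low = 0, medium = cfg$effect_medium, high = cfg$effect_high)
  out <- matrix(NA_real_, nrow = length(outcome_spec_kinds()), ncol = 3L,
                dimnames = list(outcome_spec_kinds(), exposure_levels()))
  for (kind in outcome_spec_kinds()) {
    mask <- outcome_spec(kind)$subsample(raw$anc)
    for (lev in exposure_levels()) {
      m <- counterfactual_mean(raw$lp0[mask], effect[[lev]],
                               cfg$zero_inflation, kind)
      out[kind, lev] <- mean(m)
    }
  }
  binr <- out[setdiff(rownames(out), "count"), ]
  if (any(!is.finite(binr)) || any(binr <= 0 | binr >= 1, na.rm = TRUE)) {
    stop("effect parameters drive binary counterfactual means outside (0,1)")
  }
  out
}

#' Generate a synthetic survey cohort with known counterfactual truth
#'
#' Draws a full cohort from the configured data-generating process. The
#' observed empowerment category is derived from the generated item
#' responses (WEAI-style score cut at sample quartiles); the structural
#' outcome equation takes the category label directly, so forced-assignment
#' counterfactuals are well defined.
#'
#' @param config a [dgp_config()].
#' @param compute_truth if `TRUE` (default), populate `truth` with the
#'   Monte-Carlo oracle at `n_mc` draws; disable when truth is computed
#'   once per config across many replicates.
#' @param n_mc Monte-Carlo size for the truth oracle.
#' @return list of class `synthetic_cohort`: `records` (data.frame, one row
#'   per mother), `truth` (outcome-spec x exposure-level matrix of true
#'   counterfactual means, or `NULL`), `latent_scores`, `config`.
#' @export
generate_cohort <- function(config, compute_truth = TRUE, n_mc = 1e5) {
  validate_dgp_config(config)
  raw <- simulate_raw(config, config$n_mothers, config$seed)
  records <- data.frame(
    mother_id = seq_len(config$n_mothers),
    village_id = raw$village_id,
    raw$items,
    raw$covs[, setdiff(names(raw$covs), "wealth")],
    n_inlaws = raw$n_inlaws,
    water = raw$water,
    sanitation = raw$sanitation,
    raw$assets,
    income = raw$income,
    anc_visits = as.integer(raw$anc)
  )
  records$wealth <- wealth_pca(raw$assets)
  truth <- if (compute_truth) true_counterfactual_means(config, n_mc) else NULL
  out <- list(records = records, truth = truth, latent_scores = raw$latent,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' True average treatment effect under the generator
#'
#' Difference of true counterfactual means between two exposure levels for a
#' given outcome specification, by forcing the exposure level in the
#' structural count model and averaging over a large Monte-Carlo draw of
#' covariates, village effects and subsample membership.
#'
#' @param config a [dgp_config()].
#' @param comparison character pair `c(a1, a0)` of exposure levels, e.g.
#'   `c("high", "low")`.
#' @param outcome_spec an [outcome_spec()] (or its `kind` string).
#' @param n_mc Monte-Carlo size (>= 1e5).
#' @return the true ATE `E[Y(a1)] - E[Y(a0)]` on the outcome spec's scale.
#' @export
true_ate <- function(config, comparison = c("high", "low"),
                     outcome_spec = "ge4_vs_1to3", n_mc = 1e5) {
  if (n_mc < 1e5) stop("n_mc must be at least 1e5")
  kind <- if (inherits(outcome_spec, "outcome_spec")) outcome_spec$kind else outcome_spec
  stopifnot(all(comparison %in% exposure_levels()), comparison[1] != comparison[2])
  tr <- true_counterfactual_means(config, n_mc)
  tr[kind, comparison[1]] - tr[kind, comparison[2]]
}

#' Mask covariates completely at random
#'
#' Applies the configured MCAR missingness rates to covariate columns of a
#' generated cohort. Item responses, the outcome and the village id are
#' never masked.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [dgp_config()] supplying `missing_rates` (named by
#'   covariate) and the seed.
#' @return the cohort with masked covariate values.
#' @export
inject_missingness <- function(cohort, config = cohort$config) {
  rates <- config$missing_rates
  if (length(rates) == 0) return(cohort)
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  protected <- c("anc_visits", "village_id", "mother_id",
                 config$item_schema$item)
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  for (nm in names(rates)) {
    if (nm %in% protected) stop("cannot mask items, outcome or village id")
    if (!nm %in% names(cohort$records)) stop(sprintf("unknown covariate '%s'", nm))
    mask <- stats::runif(nrow(cohort$records)) < rates[[nm]]
    cohort$records[[nm]][mask] <- NA
  }
  cohort
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' The CSV holds one row per mother; the sidecar records the generator
#' configuration and the truth matrix so an analysis can be validated
#' without regenerating.
#'
#' @param cohort a `synthetic_cohort`.
#' @param csv_path,json_path output paths.
#' @export
write_cohort <- function(cohort, csv_path, json_path = NULL) {
  utils::write.csv(cohort$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cfg <- cohort$config
    cfg$item_schema <- as.data.frame(unclass(cfg$item_schema))
    jsonlite::write_json(
      list(config = unclass(cfg),
           truth = if (!is.null(cohort$truth)) {
             cbind(data.frame(spec = rownames(cohort$truth)),
                   as.data.frame(cohort$truth))
           } else NULL),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(csv_path)
}
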