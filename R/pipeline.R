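# Analysis orchestration: imputation, outcome/exposure derivation,
# descriptive tables, subgroup rules, and the full ATE analysis.

#' Median-impute covariates with missingness indicators
#'
#' Fills each missing covariate value with the column median computed on
#' observed values and appends a 0/1 indicator column (`<name>_imputed`)
#' for every covariate with at least one missing value. The outcome and
#' exposure are never imputed.
#'
#' @param table data.frame.
#' @param covariate_cols columns eligible for imputation (numeric).
#' @return list with `table` (imputed, indicators appended) and
#'   `n_imputed` (named count of filled values per covariate).
#' @export
impute_median_with_indicators <- function(table, covariate_cols) {
  n_imputed <- integer(0)
  for (nm in covariate_cols) {
    x <- table[[nm]]
    if (!is.numeric(x)) stop(sprintf("covariate '%s' is not numeric", nm))
    miss <- is.na(x)
    if (all(miss)) stop(sprintf("covariate '%s' is fully missing", nm))
    ind <- as.integer(miss)
    table[[paste0(nm, "_imputed")]] <- ind
    if (any(miss)) {
      table[[nm]][miss] <- stats::median(x[!miss])
      n_imputed[nm] <- sum(miss)
    }
  }
  list(table = table, n_imputed = n_imputed)
}

#' Categorize antenatal care visit counts
#'
#' Maps visit counts to the categories none / 1-3 / >=4 and emits the three
#' pairwise binary outcomes with their analysis subsample masks.
#'
#' @param visits nonnegative integer vector.
#' @return list with `category` (ordered factor), and per pairwise spec a
#'   list holding the binary `outcome` and logical `mask`.
#' @export
categorize_anc <- function(visits) {
  if (any(visits < 0)) stop("visit counts must be nonnegative")
  if (any(visits != round(visits))) stop("visit counts must be integers")
  category <- cut(visits, breaks = c(-0.5, 0.5, 3.5, Inf),
                  labels = c("none", "1-3", ">=4"), ordered_result = TRUE)
  pairwise <- lapply(setdiff(outcome_spec_kinds(), "count"), function(kind) {
    spec <- outcome_spec(kind)
    list(kind = kind, outcome = spec$outcome(visits), mask = spec$subsample(visits))
  })
  names(pairwise) <- setdiff(outcome_spec_kinds(), "count")
  list(category = category, pairwise = pairwise)
}

#' Descriptive sample table by exposure category
#'
#' Mean (SD) for numeric fields and n (%) for binary fields, overall and
#' within each exposure category.
#'
#' @param table data.frame.
#' @param exposure factor of exposure categories.
#' @param numeric_cols,binary_cols column names to summarize.
#' @return data.frame, one row per field, columns `full_sample` plus one
#'   per exposure level.
#' @export
describe_sample <- function(table, exposure,
                            numeric_cols = character(),
                            binary_cols = character()) {
  groups <- c(list(full_sample = rep(TRUE, nrow(table))),
              stats::setNames(lapply(levels(exposure), function(l) exposure == l),
                              levels(exposure)))
  fmt_num <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                 stats::sd(x, na.rm = TRUE))
  fmt_bin <- function(x) sprintf("%d (%.0f%%)", sum(x, na.rm = TRUE),
                                 100 * mean(x, na.rm = TRUE))
  rows <- list(
    data.frame(field = "n",
               t(vapply(groups, function(g) as.character(sum(g)), character(1))))
  )
  for (nm in numeric_cols) {
    rows[[length(rows) + 1L]] <- data.frame(
      field = nm, t(vapply(groups, function(g) fmt_num(table[[nm]][g]),
                           character(1))))
  }
  for (nm in binary_cols) {
    rows[[length(rows) + 1L]] <- data.frame(
      field = nm, t(vapply(groups, function(g) fmt_bin(table[[nm]][g]),
                           character(1))))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("field", names(groups))
  rownames(out) <- NULL
  out
}

#' High-risk subgroup rules
#'
#' Deterministic predicates over the analysis table: `adolescent` (gave
#' birth before age 20, from current age minus child age), `parity` (more
#' than one child under 15 in the household), `inlaws` (any adults in the
#' household beyond the woman and her husband), `depression` (CESD above
#' the configured threshold, default 18 = the instrument's top-quartile
#' cutoff in this population).
#'
#' @param table analysis data.frame.
#' @param cesd_threshold depression cutoff (scores strictly greater are
#'   flagged).
#' @return named list of logical vectors.
#' @export
subgroup_rules <- function(table, cesd_threshold = 18) {
  age_at_birth <- table$age - table$child_age / 12
  list(
    adolescent = age_at_birth < 20,
    parity = table$children_u15 > 1,
    inlaws = table$n_inlaws > 0,
    depression = table$cesd > cesd_threshold
  )
}

#' Derive the analysis table from raw survey records
#'
#' Median-imputes covariates (appending indicators), scores the
#' empowerment indices (WEAI-style aggregate and subscales, SWPER-style
#' PCA components), categorizes each index by the 25/75 quantile rule on
#' the full analysis sample, computes the WAMI index and its printed-cutoff
#' category, and attaches the ANC outcome category.
#'
#' @param records data.frame in the generated-cohort schema.
#' @param schema an [item_schema()].
#' @param covariate_cols adjustment covariates to impute.
#' @return list with `table` (analysis data.frame), `covariate_cols`
#'   (covariates plus appended indicator columns), `indices` (names of the
#'   exposure index columns), `n_imputed`, `pca` (the `pca_indices` fit).
#' @export
prepare_analysis_table <- function(records, schema = item_schema(),
                                   covariate_cols = dgp_covariate_names()) {
  imp <- impute_median_with_indicators(records, covariate_cols)
  tab <- imp$table
  ind_cols <- names(tab)[endsWith(names(tab), "_imputed")]
  ind_cols <- ind_cols[vapply(ind_cols, function(nm) sum(tab[[nm]]) > 0, logical(1))]
  covs <- unique(c(covariate_cols, ind_cols))

  items <- tab[, schema$item, drop = FALSE]
  weai <- score_weai(items, schema)
  tab$emp_score <- weai$aggregate
  tab$emp_decision <- weai$decision
  tab$emp_movement <- weai$movement
  tab$emp_assets <- weai$assets
  pca <- score_swper_pca(items, schema)
  tab$pca_1 <- pca$scores[, 1]
  tab$pca_2 <- pca$scores[, 2]
  tab$pca_3 <- pca$scores[, 3]

  index_cols <- c(aggregate = "emp_score", decision = "emp_decision",
                  movement = "emp_movement", assets = "emp_assets",
                  pca_1 = "pca_1", pca_2 = "pca_2", pca_3 = "pca_3")
  for (nm in names(index_cols)) {
    tab[[paste0("cat_", nm)]] <-
      categorize_quantile(tab[[index_cols[nm]]])$category
  }

  wami <- score_wami(tab$water, tab$sanitation,
                     tab[, paste0("asset_", 1:8)], tab$edu, tab$income)
  tab$wami <- wami$score
  tab$wami_category <- wami$category

  anc <- categorize_anc(tab$anc_visits)
  tab$anc_category <- anc$category

  list(table = tab, covariate_cols = covs, indices = names(index_cols),
       index_cols = index_cols, n_imputed = imp$n_imputed, pca = pca)
}

canonical_comparisons <- function() {
  list(c("high", "low"), c("high", "medium"), c("medium", "low"))
}

drop_constant_cols <- function(tab, cols) {
  cols[vapply(cols, function(nm) stats::sd(tab[[nm]]) > 0, logical(1))]
}

# One TMLE run: restrict to the outcome spec's subsample, fit nuisances,
# target the three level means jointly, and report all three pairwise ATEs.
run_tmle_block <- function(tab, exposure_col, covariate_cols, spec,
                           library, g_library, n_folds, seed, cv,
                           g_bounds = c(0.025, 0.975)) {
  mask <- spec$subsample(tab$anc_visits)
  d <- tab[mask, , drop = FALSE]
  covariate_cols <- drop_constant_cols(d, covariate_cols)
  y <- spec$outcome(d$anc_visits)
  kind <- if (spec$kind == "count") "count" else "binary"
  d$.y <- y
  nuis <- fit_nuisance(d, ".y", exposure_col, covariate_cols,
                       library = library, g_library = g_library,
                       loss = if (kind == "binary") "nll" else "mse",
                       n_folds = n_folds, seed = seed, cv = cv,
                       g_bounds = g_bounds)
  means <- tmle_counterfactual_means(y, d[[exposure_col]], nuis, kind)
  lapply(canonical_comparisons(), function(cmp) {
    tmle_ate(means, cmp, d$village_id)
  })
}

ate_row <- function(est, index, spec_kind, stratifier, stratum) {
  data.frame(
    index = index, outcome = spec_kind,
    comparison = paste(est$comparison, collapse = "_vs_"),
    stratifier = stratifier, stratum = stratum,
    estimator = est$estimator, psi = est$psi, se = est$se,
    ci_lower = est$ci_lower, ci_upper = est$ci_upper,
    n = est$n_used, n_clusters = est$n_clusters,
    stringsAsFactors = FALSE
  )
}

#' Run the full empowerment / antenatal-care analysis
#'
#' Executes, for each selected empowerment index: TMLE average treatment
#' effects for the three pairwise comparisons and each requested outcome
#' specification on the full sample; stratified repeats per WAMI tercile
#' and per high-risk subgroup (exposure cutpoints computed once on the full
#' sample, nuisances refit per stratum); parametric G-computation for the
#' aggregate index; and a descriptive table by exposure category.
#'
#' @param records raw survey records (generated-cohort schema).
#' @param indices which indices to analyze (subset of `aggregate`,
#'   `decision`, `movement`, `assets`, `pca_1`, `pca_2`, `pca_3`).
#' @param outcomes outcome spec kinds to run.
#' @param learners,g_learners learner name vectors for the outcome
#'   regression and propensity libraries.
#' @param n_folds,seed,cv Super Learner controls.
#' @param g_bounds propensity truncation bounds.
#' @param stratify run WAMI-tercile and risk-subgroup stratified analyses.
#' @param min_stratum_n strata smaller than this are skipped (logged in
#'   `skipped`).
#' @param gcomp also run G-computation for the aggregate index.
#' @param n_boot bootstrap resamples for the G-computation CI.
#' @param schema item schema.
#' @return list of class `anc_analysis`: `estimates` (tidy data.frame),
#'   `descriptive`, `n_imputed`, `skipped`, `config`.
#' @export
run_analysis <- function(records,
                         indices = c("aggregate", "decision", "movement",
                                     "assets"),
                         outcomes = outcome_spec_kinds(),
                         learners = c("glm", "lasso", "ridge"),
                         g_learners = learners,
                         n_folds = 10, seed = 2019L, cv = TRUE,
                         g_bounds = c(0.025, 0.975),
                         stratify = TRUE, min_stratum_n = 100L,
                         gcomp = TRUE, n_boot = 200L,
                         schema = item_schema()) {
  prep <- prepare_analysis_table(records, schema)
  tab <- prep$table
  lib <- learner_library(learners)
  g_lib <- learner_library(g_learners)
  rows <- list()
  skipped <- character(0)

  add <- function(row) rows[[length(rows) + 1L]] <<- row

  strata <- list(full = list(stratifier = "none", masks = list(full = rep(TRUE, nrow(tab)))))
  if (stratify) {
    strata$wami <- list(
      stratifier = "wami_tercile",
      masks = stats::setNames(
        lapply(levels(tab$wami_category), function(l) tab$wami_category == l),
        levels(tab$wami_category))
    )
    sg <- subgroup_rules(tab)
    strata$risk <- list(stratifier = "risk_subgroup", masks = sg)
  }

  for (index in indices) {
    exposure_col <- paste0("cat_", index)
    for (kind in outcomes) {
      spec <- outcome_spec(kind)
      for (block in strata) {
        for (stratum in names(block$masks)) {
          mask <- block$masks[[stratum]]
          sub <- tab[mask, , drop = FALSE]
          if (nrow(sub) < min_stratum_n && block$stratifier != "none") {
            skipped <- c(skipped, sprintf("%s/%s/%s/%s: n=%d below minimum %d",
                                          index, kind, block$stratifier,
                                          stratum, nrow(sub), min_stratum_n))
            next
          }
          ests <- tryCatch(
            run_tmle_block(sub, exposure_col, prep$covariate_cols, spec,
                           lib, g_lib, n_folds, seed, cv, g_bounds),
            error = function(e) {
              skipped <<- c(skipped, sprintf("%s/%s/%s/%s: %s", index, kind,
                                             block$stratifier, stratum,
                                             conditionMessage(e)))
              NULL
            }
          )
          if (is.null(ests)) next
          for (est in ests) {
            add(ate_row(est, index, kind, block$stratifier, stratum))
          }
        }
      }
    }
  }

  if (gcomp && "aggregate" %in% indices) {
    for (kind in outcomes) {
      spec <- outcome_spec(kind)
      mask <- spec$subsample(tab$anc_visits)
      d <- tab[mask, , drop = FALSE]
      d$.y <- spec$outcome(d$anc_visits)
      gcovs <- drop_constant_cols(d, prep$covariate_cols)
      for (cmp in canonical_comparisons()) {
        est <- gcomp_ate(d, ".y", "cat_aggregate", gcovs, cmp,
                         outcome_kind = if (kind == "count") "count" else "binary",
                         n_boot = n_boot, seed = seed)
        add(ate_row(est, "aggregate", kind, "none", "full"))
      }
    }
  }

  descriptive <- describe_sample(
    tab, tab$cat_aggregate,
    numeric_cols = intersect(c("age", "cesd", "edu", "edu_diff", "wealth",
                               "income", "wami", "hh_members", "n_inlaws",
                               "children_u15", "child_age", "emp_score",
                               "anc_visits"), names(tab)),
    binary_cols = intersect(c("water", "sanitation"), names(tab))
  )

  out <- list(
    estimates = do.call(rbind, rows),
    descriptive = descriptive,
    n_imputed = prep$n_imputed,
    skipped = skipped,
    config = list(indices = indices, outcomes = outcomes, learners = learners,
                  g_learners = g_learners, n_folds = n_folds, seed = seed,
                  g_bounds = g_bounds, min_stratum_n = min_stratum_n)
  )
  class(out) <- "anc_analysis"
  out
}

#' Serialize / reload an analysis result bundle
#'
#' Writes the tidy estimate table as CSV and the full bundle (estimates,
#' descriptive table, provenance) as JSON; `read_analysis` restores the
#' bundle from the JSON losslessly.
#'
#' @param result an `anc_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_analysis <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(estimates = result$estimates, descriptive = result$descriptive,
         n_imputed = as.list(result$n_imputed), skipped = result$skipped,
         config = result$config),
    file.path(dir, "analysis.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows"
  )
  invisible(file.path(dir, "analysis.json"))
}

#' @rdname write_analysis
#' @param path path to `analysis.json`.
#' @export
read_analysis <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(estimates = raw$estimates, descriptive = raw$descriptive,
              n_imputed = unlist(raw$n_imputed), skipped = raw$skipped,
              config = raw$config)
  class(out) <- "anc_analysis"
  out
}
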