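# Nuisance estimation: outcome regression Qbar(A, W) and propensity
# g(a | W), each by Super Learner, plus positivity bounding.

encode_features <- function(df) {
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Fit the outcome regression at every exposure level
#'
#' Fits one Super Learner to (A, W) and produces predictions with the
#' exposure set to each level for every record. Binary predictions are
#' bounded away from 0 and 1 by 1e-6.
#'
#' @param data data.frame holding the exposure, covariates and outcome.
#' @param outcome_col,exposure_col,covariate_cols column names; the exposure
#'   column must be a factor with levels low/medium/high.
#' @param library learner library (see [learner_library()]).
#' @param loss `"nll"` for binary outcomes, `"mse"` for continuous.
#' @param n_folds,seed,cv passed to [fit_super_learner()].
#' @return list with `qbar` (n x 3 matrix, columns low/medium/high),
#'   `qbar_obs` (prediction at the observed exposure) and `fit`.
#' @export
fit_outcome_regression <- function(data, outcome_col, exposure_col,
                                   covariate_cols, library = learner_library(),
                                   loss = c("nll", "mse"), n_folds = 10,
                                   seed = 1L, cv = TRUE) {
  loss <- match.arg(loss)
  a <- data[[exposure_col]]
  stopifnot(is.factor(a), identical(levels(a), exposure_levels()))
  y <- data[[outcome_col]]
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; degenerate fit")
  }
  df <- data.frame(a = a, data[, covariate_cols, drop = FALSE])
  x <- encode_features(df)
  sl <- fit_super_learner(x, y, library, n_folds = n_folds, loss = loss,
                          seed = seed, cv = cv)
  qbar <- sapply(exposure_levels(), function(lev) {
    df_a <- df
    df_a$a <- factor(lev, levels = exposure_levels())
    sl$predict(encode_features(df_a))
  })
  if (loss == "nll") qbar <- pmin(pmax(qbar, 1e-6), 1 - 1e-6)
  qbar_obs <- qbar[cbind(seq_len(nrow(qbar)), as.integer(a))]
  list(qbar = qbar, qbar_obs = qbar_obs, fit = sl)
}

#' Fit the categorical propensity score
#'
#' Estimates P(A = a | W) for the three ordered exposure levels by two
#' nested binary Super Learners: P(A = low | W) on the full sample, then
#' P(A = high | A != low, W) among the non-low records. The three level
#' probabilities are assembled from the factorization (and renormalized,
#' which is a no-op up to floating point), so every binary learner in the
#' library is reused unchanged and rows sum to one.
#'
#' @inheritParams fit_outcome_regression
#' @param min_level_n minimum observations per exposure level.
#' @return list with `g` (n x 3 row-stochastic matrix) and `fits`.
#' @export
fit_propensity <- function(data, exposure_col, covariate_cols,
                           library = learner_library(), n_folds = 10,
                           seed = 1L, cv = TRUE, min_level_n = 10L) {
  a <- data[[exposure_col]]
  stopifnot(is.factor(a), identical(levels(a), exposure_levels()))
  counts <- table(a)
  if (any(counts < min_level_n)) {
    stop(sprintf(
      "exposure level(s) %s have fewer than %d observations; collapse levels before analysis",
      paste(names(counts)[counts < min_level_n], collapse = ", "), min_level_n))
  }
  x <- encode_features(data[, covariate_cols, drop = FALSE])
  sl_low <- fit_super_learner(x, as.numeric(a == "low"), library,
                              n_folds = n_folds, loss = "nll",
                              seed = seed + 1L, cv = cv)
  p_low <- sl_low$predict(x)
  not_low <- a != "low"
  sl_high <- fit_super_learner(x[not_low, , drop = FALSE],
                               as.numeric(a[not_low] == "high"), library,
                               n_folds = n_folds, loss = "nll",
                               seed = seed + 2L, cv = cv)
  p_high_cond <- sl_high$predict(x)
  g <- cbind(low = p_low,
             medium = (1 - p_low) * (1 - p_high_cond),
             high = (1 - p_low) * p_high_cond)
  g <- g / rowSums(g)
  list(g = g, fits = list(low = sl_low, high_given_not_low = sl_high))
}

#' Bound propensity scores away from 0 and 1
#'
#' Truncates each cell of the propensity matrix to `[lo, hi]` and then
#' renormalizes rows to sum to one; reports the fraction of truncated
#' cells.
#'
#' @param g n x 3 matrix of exposure-level probabilities.
#' @param lo,hi truncation bounds, `0 < lo < hi < 1`.
#' @return list with `g` (bounded, renormalized), `truncation_frac`,
#'   and the bounds.
#' @export
bound_propensity <- function(g, lo = 0.025, hi = 0.975) {
  if (!(lo > 0 && lo < hi && hi < 1)) stop("need 0 < lo < hi < 1")
  truncated <- g < lo | g > hi
  gb <- pmin(pmax(g, lo), hi)
  gb <- gb / rowSums(gb)
  list(g = gb, truncation_frac = mean(truncated), lo = lo, hi = hi)
}

#' Assemble nuisance estimates for TMLE
#'
#' Convenience wrapper fitting the outcome regression and the bounded
#' propensity on one analysis table.
#'
#' @inheritParams fit_outcome_regression
#' @param g_library learner library for the propensity (defaults to
#'   `library`).
#' @param g_bounds length-2 truncation bounds for the propensity.
#' @return object of class `nuisance_estimates`: `qbar` (n x 3), `qbar_obs`,
#'   `g` (n x 3, bounded), `truncation_frac`, `fits`.
#' @export
fit_nuisance <- function(data, outcome_col, exposure_col, covariate_cols,
                         library = learner_library(),
                         g_library = library, loss = c("nll", "mse"),
                         n_folds = 10, seed = 1L, cv = TRUE,
                         g_bounds = c(0.025, 0.975)) {
  loss <- match.arg(loss)
  qr <- fit_outcome_regression(data, outcome_col, exposure_col,
                               covariate_cols, library, loss = loss,
                               n_folds = n_folds, seed = seed, cv = cv)
  pr <- fit_propensity(data, exposure_col, covariate_cols, g_library,
                       n_folds = n_folds, seed = seed + 100L, cv = cv)
  gb <- bound_propensity(pr$g, g_bounds[1], g_bounds[2])
  new_nuisance(qr$qbar, gb$g, qbar_obs = qr$qbar_obs,
               truncation_frac = gb$truncation_frac,
               fits = list(q = qr$fit, g = pr$fits))
}

#' Construct nuisance estimates from explicit matrices
#'
#' Used to supply externally computed (e.g. saturated or true) nuisance
#' values to the targeting step.
#'
#' @param qbar n x 3 outcome-regression matrix (columns low/medium/high).
#' @param g n x 3 propensity matrix (rows summing to 1).
#' @param qbar_obs optional prediction at the observed exposure; required
#'   by targeting, can be derived later via [qbar_at()].
#' @param truncation_frac,fits diagnostics.
#' @return object of class `nuisance_estimates`.
#' @export
new_nuisance <- function(qbar, g, qbar_obs = NULL, truncation_frac = 0,
                         fits = NULL) {
  qbar <- as.matrix(qbar); g <- as.matrix(g)
  stopifnot(ncol(qbar) == 3L, ncol(g) == 3L, nrow(qbar) == nrow(g))
  colnames(qbar) <- colnames(g) <- exposure_levels()
  out <- list(qbar = qbar, qbar_obs = qbar_obs, g = g,
              truncation_frac = truncation_frac, fits = fits)
  class(out) <- "nuisance_estimates"
  out
}

#' @rdname new_nuisance
#' @param nuisance a `nuisance_estimates` object.
#' @param a observed exposure factor.
#' @export
qbar_at <- function(nuisance, a) {
  nuisance$qbar[cbind(seq_len(nrow(nuisance$qbar)), as.integer(a))]
}

#' Saturated (stratum-mean) nuisance estimates for discrete covariates
#'
#' Computes the outcome regression as exact cell means of the outcome over
#' (exposure x covariate-stratum) cells, and the propensity as empirical
#' exposure proportions within each covariate stratum. Every stratum must
#' contain all three exposure levels.
#'
#' @param data data.frame with discrete covariates.
#' @param outcome_col,exposure_col,covariate_cols column names.
#' @return a `nuisance_estimates` object.
#' @export
saturated_nuisance <- function(data, outcome_col, exposure_col, covariate_cols) {
  a <- data[[exposure_col]]
  stopifnot(is.factor(a), identical(levels(a), exposure_levels()))
  y <- data[[outcome_col]]
  stratum <- interaction(data[, covariate_cols, drop = FALSE], drop = TRUE)
  n <- nrow(data)
  qbar <- matrix(NA_real_, n, 3L)
  g <- matrix(NA_real_, n, 3L)
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    for (i in seq_along(exposure_levels())) {
      lev <- exposure_levels()[i]
      cell <- idx[a[idx] == lev]
      if (length(cell) == 0) {
        stop(sprintf("stratum '%s' lacks exposure level '%s'", s, lev))
      }
      qbar[idx, i] <- mean(y[cell])
      g[idx, i] <- length(cell) / length(idx)
    }
  }
  new_nuisance(qbar, g,
               qbar_obs = qbar[cbind(seq_len(n), as.integer(a))])
}
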