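# Targeted maximum likelihood estimation of counterfactual means for a
# three-level exposure, with village-clustered influence-curve inference.

logit_bounded <- function(p, eps = 1e-12) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# Solve the intercept-only weighted logistic fluctuation for one exposure
# level: find eps with sum_i H_i * (y_i - expit(logit(qbar_i) + eps)) = 0,
# where H_i = 1(A_i = a) / g_i(a). The score is strictly decreasing in eps,
# so the root is unique; it is located to near machine precision, which is
# what drives the post-targeting mean of the efficient influence curve to
# zero.
solve_fluctuation <- function(y, qbar_logit, h) {
  idx <- which(h > 0)
  if (length(idx) == 0) stop("no observations at this exposure level")
  score <- function(eps) {
    sum(h[idx] * (y[idx] - stats::plogis(qbar_logit[idx] + eps)))
  }
  s0 <- score(0)
  # already solved (e.g. saturated initial fit, possibly with clamped
  # degenerate cells): leave the fluctuation at zero
  if (abs(s0) <= 1e-9 * max(1, sum(h[idx]))) return(0)
  root <- tryCatch(
    stats::uniroot(score, interval = c(-4, 4), extendInt = "downX",
                   tol = .Machine$double.eps^0.75, maxiter = 1000)$root,
    error = function(e) NULL
  )
  if (is.null(root)) {
    # no interior root (degenerate outcome, e.g. all 0 or all 1 in the
    # level): the MLE sits at the boundary; take the eps minimizing |score|
    opt <- stats::optimize(function(e) abs(score(e)), c(-30, 30),
                           tol = .Machine$double.eps^0.5)
    if (abs(score(opt$minimum)) > 1e-6 * max(1, sum(h[idx]))) {
      stop("TMLE fluctuation did not converge (residual score ",
           signif(score(opt$minimum), 3), ")")
    }
    root <- opt$minimum
  }
  root
}

#' Targeted counterfactual means for a three-level exposure
#'
#' Updates the initial outcome regression with one intercept-only logistic
#' fluctuation per exposure level, using the clever covariate
#' `H_a = 1(A = a) / g(a | W)` as the fluctuation weight, and returns the
#' targeted mean `psi_a = mean(qbar*(a, W))` per level together with the
#' per-record efficient influence curve values
#' `EIC_a = H_a (Y - qbar*(A, W)) + qbar*(a, W) - psi_a`.
#'
#' Count outcomes are min-max scaled to `[0, 1]` over their observed range
#' before the logistic fluctuation and the means and influence curves are
#' back-transformed to the visit scale.
#'
#' @param y outcome vector (binary 0/1, or nonnegative count).
#' @param a exposure factor with levels low/medium/high.
#' @param nuisance a `nuisance_estimates` object on the same records, with
#'   `qbar` on the scale of `y`.
#' @param outcome_kind `"binary"` or `"count"`.
#' @return object of class `tmle_means`: `psi` (named length 3), `eic`
#'   (n x 3 matrix), `epsilon` (fluctuation coefficients), `mean_eic`
#'   (post-targeting score per level), `scale` (min/max used for counts),
#'   `n`.
#' @export
tmle_counterfactual_means <- function(y, a, nuisance,
                                      outcome_kind = c("binary", "count")) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(inherits(nuisance, "nuisance_estimates"))
  n <- length(y)
  if (n == 0) stop("empty analysis subsample")
  if (nrow(nuisance$qbar) != n) stop("nuisance predictions do not match records")
  stopifnot(is.factor(a), identical(levels(a), exposure_levels()))

  if (outcome_kind == "binary") {
    if (any(!y %in% c(0, 1))) stop("binary outcome must be 0/1")
    ymin <- 0; ymax <- 1
    ys <- y
    qs <- nuisance$qbar
  } else {
    if (any(y < 0)) stop("count outcome must be nonnegative")
    ymin <- min(y); ymax <- max(y)
    if (ymax <= ymin) stop("outcome is constant; targeting undefined")
    ys <- (y - ymin) / (ymax - ymin)
    qs <- (nuisance$qbar - ymin) / (ymax - ymin)
    qs <- pmin(pmax(qs, 1e-6), 1 - 1e-6)
  }
  rng <- ymax - ymin

  qlogit <- apply(qs, 2, logit_bounded)
  a_int <- as.integer(a)
  psi <- numeric(3)
  epsilon <- numeric(3)
  eic <- matrix(NA_real_, n, 3L)
  mean_eic <- numeric(3)
  qstar <- matrix(NA_real_, n, 3L)
  for (i in 1:3) {
    h <- as.numeric(a_int == i) / nuisance$g[, i]
    epsilon[i] <- solve_fluctuation(ys, qlogit[, i], h)
    qstar[, i] <- stats::plogis(qlogit[, i] + epsilon[i])
    psi_s <- mean(qstar[, i])
    eic_s <- h * (ys - qstar[, i]) + qstar[, i] - psi_s
    psi[i] <- ymin + rng * psi_s
    eic[, i] <- rng * eic_s
    mean_eic[i] <- mean(eic[, i])
  }
  names(psi) <- names(epsilon) <- names(mean_eic) <- exposure_levels()
  colnames(eic) <- exposure_levels()
  out <- list(psi = psi, eic = eic, epsilon = epsilon, mean_eic = mean_eic,
              qstar = qstar, scale = c(min = ymin, max = ymax), n = n)
  class(out) <- "tmle_means"
  out
}

#' Cluster-robust influence-curve standard error
#'
#' `se^2 = (1/n^2) * sum over clusters of (sum of within-cluster influence
#' values)^2`. With singleton clusters this reduces exactly to the
#' unclustered influence-curve standard error `sqrt(sum(eic^2)) / n`.
#'
#' @param eic per-record influence-curve values.
#' @param cluster_ids cluster (village) identifier per record.
#' @return the standard error.
#' @export
cluster_variance <- function(eic, cluster_ids) {
  if (length(eic) != length(cluster_ids)) {
    stop("every record needs a cluster id")
  }
  if (length(unique(cluster_ids)) < 2L) {
    stop("need at least two clusters for a clustered standard error")
  }
  sums <- tapply(eic, cluster_ids, sum)
  sqrt(sum(sums^2)) / length(eic)
}

#' Pairwise average treatment effect from targeted means
#'
#' `psi = psi_{a1} - psi_{a0}` with influence curve
#' `EIC_{a1} - EIC_{a0}`, village-clustered standard error and 95% Wald
#' interval. Because all three level means are targeted jointly on the same
#' records, the pairwise effects are exactly additive:
#' `psi(high, low) = psi(high, medium) + psi(medium, low)`.
#'
#' @param means a `tmle_means` object.
#' @param comparison character pair `c(a1, a0)`.
#' @param cluster_ids village identifier per record.
#' @return object of class `ate_estimate`: `psi`, `se`, `ci_lower`,
#'   `ci_upper`, `n_used`, `n_clusters`, `eic`, `comparison`, `diagnostics`.
#' @export
tmle_ate <- function(means, comparison, cluster_ids) {
  stopifnot(inherits(means, "tmle_means"))
  stopifnot(all(comparison %in% exposure_levels()), comparison[1] != comparison[2])
  if (length(cluster_ids) != means$n) stop("cluster ids do not match records")
  eic <- means$eic[, comparison[1]] - means$eic[, comparison[2]]
  psi <- unname(means$psi[comparison[1]] - means$psi[comparison[2]])
  se <- cluster_variance(eic, cluster_ids)
  out <- list(
    estimator = "tmle",
    psi = psi, se = se,
    ci_lower = psi - stats::qnorm(0.975) * se,
    ci_upper = psi + stats::qnorm(0.975) * se,
    n_used = means$n, n_clusters = length(unique(cluster_ids)),
    eic = eic, comparison = comparison,
    diagnostics = list(mean_eic = means$mean_eic, epsilon = means$epsilon)
  )
  class(out) <- "ate_estimate"
  out
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("%s ATE %s - %s: %.4f (SE %.4f, 95%% CI %.4f to %.4f, n = %d, clusters = %d)\n",
              toupper(x$estimator), x$comparison[1], x$comparison[2],
              x$psi, x$se, x$ci_lower, x$ci_upper, x$n_used, x$n_clusters))
  invisible(x)
}

#' Parametric G-computation of a pairwise treatment effect
#'
#' Fits a single parametric outcome model (main-terms logistic for binary
#' outcomes, linear for counts, by default), predicts with the exposure
#' forced to each level, and differences the prediction means. Confidence
#' intervals come from a nonparametric cluster (village) bootstrap:
#' villages are resampled with replacement and the percentile interval of
#' the re-estimated effects is reported.
#'
#' @param data analysis data.frame.
#' @param outcome_col,exposure_col,covariate_cols column names.
#' @param comparison character pair `c(a1, a0)`.
#' @param outcome_kind `"binary"` or `"count"`.
#' @param cluster_col village id column.
#' @param formula optional model formula; default is main terms in the
#'   exposure and covariates.
#' @param n_boot bootstrap resamples (warning below 50; 0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `ate_estimate` with `level_means` attached
#'   (so pairwise effects telescope exactly).
#' @export
gcomp_ate <- function(data, outcome_col, exposure_col, covariate_cols,
                      comparison, outcome_kind = c("binary", "count"),
                      cluster_col = "village_id", formula = NULL,
                      n_boot = 1000, seed = 1L) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(all(comparison %in% exposure_levels()))
  if (n_boot > 0 && n_boot < 50) {
    warning("fewer than 50 bootstrap resamples; percentile CI will be unstable")
  }
  if (is.null(formula)) {
    formula <- stats::as.formula(paste(
      outcome_col, "~", paste(c(exposure_col, covariate_cols), collapse = " + ")))
  }
  family <- if (outcome_kind == "binary") stats::binomial() else stats::gaussian()

  level_means_fun <- function(d) {
    fit <- tryCatch(stats::glm(formula, data = d, family = family),
                    error = function(e) stop("G-computation model failed to fit: ",
                                             conditionMessage(e)))
    vapply(exposure_levels(), function(lev) {
      d_a <- d
      d_a[[exposure_col]] <- factor(lev, levels = exposure_levels())
      mean(stats::predict(fit, newdata = d_a, type = "response"))
    }, numeric(1))
  }
  lm0 <- level_means_fun(data)
  psi <- unname(lm0[comparison[1]] - lm0[comparison[2]])

  ci <- c(NA_real_, NA_real_); se <- NA_real_
  if (identical(comparison[1], comparison[2])) {
    psi <- 0; ci <- c(0, 0); se <- 0
  } else if (n_boot > 0) {
    set.seed(seed)
    clusters <- unique(data[[cluster_col]])
    boot_psi <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(clusters, length(clusters), replace = TRUE)
      idx <- unlist(lapply(pick, function(cl) which(data[[cluster_col]] == cl)),
                    use.names = FALSE)
      bm <- tryCatch(level_means_fun(data[idx, , drop = FALSE]),
                     error = function(e) rep(NA_real_, 3))
      bm[comparison[1]] <- unname(bm[comparison[1]])
      unname(bm[comparison[1]] - bm[comparison[2]])
    }, numeric(1))
    boot_psi <- boot_psi[is.finite(boot_psi)]
    if (length(boot_psi) >= 2) {
      ci <- unname(stats::quantile(boot_psi, c(0.025, 0.975), type = 7))
      se <- stats::sd(boot_psi)
    }
  }
  out <- list(
    estimator = "gcomp",
    psi = psi, se = se, ci_lower = ci[1], ci_upper = ci[2],
    n_used = nrow(data),
    n_clusters = length(unique(data[[cluster_col]])),
    eic = NULL, comparison = comparison,
    level_means = lm0,
    diagnostics = list(n_boot = n_boot)
  )
  class(out) <- "ate_estimate"
  out
}
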