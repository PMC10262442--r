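test_that("saturated nuisance reproduces hand-computed stratum means", {
  d <- toy12()
  nuis <- saturated_nuisance(d, "y", "a", "w")
  # w=0 cells have means 1/2, 1/2, 1 and w=1 cells 0, 1/2, 1; assert
  # against cell means recomputed directly from the table
  for (lev in c("low", "medium", "high")) {
    for (w in c(0, 1)) {
      cell_mean <- mean(d$y[d$a == lev & d$w == w])
      expect_equal(unique(nuis$qbar[d$w == w, lev]), cell_mean)
    }
  }
  expect_true(all(abs(rowSums(nuis$g) - 1) < 1e-12))
  # empirical propensities are cell shares
  for (w in c(0, 1)) {
    expect_equal(unique(nuis$g[d$w == w, "low"]),
                 mean(d$a[d$w == w] == "low"))
  }
})

test_that("outcome regression predicts at all levels, bounded and order-invariant", {
  f <- shared_ge4_table()
  d <- f$data
  qr <- fit_outcome_regression(d, ".y", "cat_aggregate", f$covariate_cols,
                               learner_library("glm"), loss = "nll",
                               n_folds = 5, seed = 2, cv = FALSE)
  expect_equal(dim(qr$qbar), c(nrow(d), 3L))
  expect_true(all(qr$qbar >= 1e-6 & qr$qbar <= 1 - 1e-6))
  perm <- sample(nrow(d))
  qr2 <- fit_outcome_regression(d[perm, ], ".y", "cat_aggregate",
                                f$covariate_cols, learner_library("glm"),
                                loss = "nll", n_folds = 5, seed = 2, cv = FALSE)
  expect_equal(qr2$qbar[order(perm), ], qr$qbar, tolerance = 1e-8)
  expect_error(
    fit_outcome_regression(transform(d, .y = 0), ".y", "cat_aggregate",
                           f$covariate_cols, learner_library("glm"),
                           cv = FALSE),
    "constant"
  )
})

test_that("null exposure effect shrinks the fitted level gap with n", {
  gap_at_n <- function(n, seed) {
    cfg <- dgp_config(n_mothers = n, seed = seed,
                      effect_medium = 0, effect_high = 0)
    prep <- prepare_analysis_table(generate_cohort(cfg, compute_truth = FALSE)$records)
    tab <- prep$table
    tab$.y <- as.numeric(tab$anc_visits >= 4)
    qr <- fit_outcome_regression(tab, ".y", "cat_aggregate",
                                 prep$covariate_cols, learner_library("glm"),
                                 loss = "nll", n_folds = 5, seed = seed,
                                 cv = FALSE)
    max(abs(colMeans(qr$qbar) - mean(colMeans(qr$qbar))))
  }
  expect_lt(gap_at_n(8000L, 61L), 0.025)
})

test_that("propensity rows are simplex vectors near the marginal shares", {
  f <- shared_ge4_table()
  pr <- fit_propensity(f$data, "cat_aggregate", f$covariate_cols,
                       learner_library("glm"), n_folds = 5, seed = 5,
                       cv = FALSE)
  expect_true(all(abs(rowSums(pr$g) - 1) < 1e-12))
  # exposure is derived from a quartile cut, so marginal shares are
  # approximately (0.25, 0.50, 0.25); weak confounding keeps g near them
  expect_lt(abs(mean(pr$g[, "low"]) - 0.25), 0.05)
  expect_lt(abs(mean(pr$g[, "medium"]) - 0.50), 0.05)

  small <- f$data[1:40, ]
  small$cat_aggregate <- factor(rep(c("low", "medium"), 20),
                                levels = levels(f$data$cat_aggregate))
  expect_error(
    fit_propensity(small, "cat_aggregate", f$covariate_cols,
                   learner_library("glm"), cv = FALSE),
    "fewer than"
  )
})

test_that("a confounded propensity beats the intercept-only model on log-loss", {
  cfg <- dgp_config_dr(n_mothers = 3000L, seed = 19L)
  prep <- prepare_analysis_table(generate_cohort(cfg, compute_truth = FALSE)$records)
  tab <- prep$table
  a <- tab$cat_aggregate
  pr <- fit_propensity(tab, "cat_aggregate", prep$covariate_cols,
                       learner_library("glm"), n_folds = 5, seed = 6,
                       cv = FALSE)
  obs <- cbind(a == "low", a == "medium", a == "high")
  logloss <- function(p) -mean(log(pmax(rowSums(p * obs), 1e-12)))
  marginal <- matrix(rep(colMeans(obs), each = nrow(obs)), nrow(obs))
  expect_lt(logloss(pr$g), logloss(marginal))
})

test_that("propensity bounding truncates and renormalizes", {
  g <- rbind(c(0.001, 0.499, 0.5), c(0.2, 0.5, 0.3))
  b <- bound_propensity(g, 0.025, 0.975)
  expect_true(all(abs(rowSums(b$g) - 1) < 1e-12))
  expect_equal(b$truncation_frac, 1 / 6)
  # already-inside rows unchanged
  expect_equal(b$g[2, ], c(0.2, 0.5, 0.3), ignore_attr = TRUE)
  # the truncated cell hits the bound before renormalization
  expect_equal(pmin(pmax(g, 0.025), 0.975)[1, 1], 0.025)
  expect_error(bound_propensity(g, 0.5, 0.4), "lo < hi")
})
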