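test_that("TMLE, G-computation and hand standardization agree on the toy cohort", {
  fx <- toy_fixture()
  res <- check_saturated_equivalence(fx)
  expect_lt(res$max_discrepancy, 1e-6)
  # and the targeted level means reproduce the shipped hand values
  nuis <- saturated_nuisance(fx$data, "y", "a", "w")
  means <- tmle_counterfactual_means(fx$data$y, fx$data$a, nuis, "binary")
  expect_equal(unname(means$psi), unname(fx$hand_psi), tolerance = 1e-7)
})

test_that("the oracle check is invariant to row permutation and zero outcomes", {
  fx <- toy_fixture()
  set.seed(14)
  perm <- sample(nrow(fx$data))
  res_p <- check_saturated_equivalence(list(data = fx$data[perm, ]))
  res_0 <- check_saturated_equivalence(fx)
  expect_equal(res_p$tmle, res_0$tmle, tolerance = 1e-10)

  zero <- fx$data
  zero$y <- 0
  res_z <- check_saturated_equivalence(list(data = zero))
  expect_lt(max(abs(unlist(res_z[c("tmle", "gcomp", "hand")]))), 1e-6)
})

test_that("correct initial qbar leaves the fluctuation at zero", {
  d <- toy12()
  nuis <- saturated_nuisance(d, "y", "a", "w")
  means <- tmle_counterfactual_means(d$y, d$a, nuis, "binary")
  expect_lt(max(abs(means$epsilon)), 1e-8)
  # psi equals the plug-in mean of the initial qbar
  expect_equal(unname(means$psi), unname(colMeans(nuis$qbar)),
               tolerance = 1e-9)
})

test_that("targeting solves the score equation on a fitted cohort", {
  tm <- shared_tmle()
  expect_lt(max(abs(tm$means$mean_eic)), 1e-8)
})

test_that("pairwise TMLE effects are exactly additive with joint targeting", {
  tm <- shared_tmle()
  v <- tm$data$village_id
  hl <- tmle_ate(tm$means, c("high", "low"), v)
  hm <- tmle_ate(tm$means, c("high", "medium"), v)
  ml <- tmle_ate(tm$means, c("medium", "low"), v)
  expect_equal(hl$psi, hm$psi + ml$psi, tolerance = 1e-12)
  expect_true(hl$ci_lower <= hl$psi && hl$psi <= hl$ci_upper)
  expect_true(abs(hl$psi) <= 1)
  # identical levels give a zero effect with centred influence curve
  same <- tmle_ate(tm$means, c("high", "low"), v)
  eic_self <- tm$means$eic[, "high"] - tm$means$eic[, "high"]
  expect_equal(mean(eic_self), 0)
  expect_equal(same$n_used, nrow(tm$data))
})

test_that("count-outcome targeting back-transforms to the visit scale", {
  co <- shared_cohort()
  prep <- prepare_analysis_table(co$records)
  tab <- prep$table
  tab$.y <- as.numeric(tab$anc_visits)
  nuis <- fit_nuisance(tab, ".y", "cat_aggregate", prep$covariate_cols,
                       library = learner_library("glm"), loss = "mse",
                       n_folds = 5, seed = 3, cv = FALSE)
  means <- tmle_counterfactual_means(tab$.y, tab$cat_aggregate, nuis, "count")
  expect_true(all(means$psi >= min(tab$.y) & means$psi <= max(tab$.y)))
  expect_lt(max(abs(means$mean_eic)), 1e-8)
  ate <- tmle_ate(means, c("high", "low"), tab$village_id)
  expect_true(abs(ate$psi) <= diff(range(tab$.y)))
  expect_gt(ate$psi, 0)
})

test_that("cluster variance matches hand computation and its reductions", {
  eic <- c(1, -2, 3, 0, -1, -1)
  cl <- c("a", "a", "b", "b", "c", "c")
  # cluster sums (-1, 3, -2) -> se = sqrt(1 + 9 + 4) / 6
  expect_equal(cluster_variance(eic, cl), sqrt(14) / 6)
  # singleton clusters reduce to the unclustered IC standard error
  expect_equal(cluster_variance(eic, seq_along(eic)),
               sqrt(sum(eic^2)) / length(eic))
  # duplicating every record within its cluster doubles the sums and n,
  # leaving the clustered se unchanged: sqrt(4*14) / 12 = sqrt(14) / 6
  expect_equal(cluster_variance(rep(eic, 2), rep(cl, 2)), sqrt(14) / 6)
  expect_equal(cluster_variance(rep(0, 6), cl), 0)
  expect_error(cluster_variance(eic, rep("a", 6)), "two clusters")
  expect_error(cluster_variance(eic, c("a", "b")), "cluster id")
})

test_that("G-computation telescopes exactly and handles degenerate comparisons", {
  f <- shared_ge4_table()
  d <- f$data
  covs <- f$covariate_cols
  g_hl <- gcomp_ate(d, ".y", "cat_aggregate", covs, c("high", "low"),
                    outcome_kind = "binary", n_boot = 0)
  g_hm <- gcomp_ate(d, ".y", "cat_aggregate", covs, c("high", "medium"),
                    outcome_kind = "binary", n_boot = 0)
  g_ml <- gcomp_ate(d, ".y", "cat_aggregate", covs, c("medium", "low"),
                    outcome_kind = "binary", n_boot = 0)
  expect_equal(g_hl$psi, g_hm$psi + g_ml$psi, tolerance = 1e-12)

  same <- gcomp_ate(d, ".y", "cat_aggregate", covs, c("high", "high"),
                    outcome_kind = "binary", n_boot = 0)
  expect_equal(same$psi, 0)
  expect_equal(c(same$ci_lower, same$ci_upper), c(0, 0))

  # cluster bootstrap produces a CI around the estimate
  expect_warning(
    g_ci <- gcomp_ate(d[1:400, ], ".y", "cat_aggregate", covs,
                      c("high", "low"), outcome_kind = "binary",
                      n_boot = 40, seed = 2),
    "resamples"
  )
  expect_true(is.finite(g_ci$ci_lower) && is.finite(g_ci$ci_upper))
  expect_true(g_ci$ci_lower <= g_ci$ci_upper)
})
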