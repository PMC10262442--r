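test_that("experiment summaries satisfy the RMSE decomposition", {
  est <- c(0.12, 0.18, 0.15, 0.10, 0.20)
  res <- experiment_result(est, truth = 0.15, ses = rep(0.03, 5),
                           covered = c(1, 1, 0, 1, 1), n = 100L)
  expect_equal(res$rmse^2, res$bias^2 + res$sd^2, tolerance = 1e-12)
  expect_equal(res$coverage, 0.8)
  expect_equal(res$replicates, 5L)
})

test_that("replicate seeds derive deterministically from the master seed", {
  expect_identical(ancempower:::derive_seeds(5L, 10L),
                   ancempower:::derive_seeds(5L, 10L))
  expect_false(identical(ancempower:::derive_seeds(5L, 10L),
                         ancempower:::derive_seeds(6L, 10L)))
})

test_that("a small recovery experiment runs for both estimators", {
  cfg <- dgp_config()
  truth <- 0.15  # nominal; small runs only check plumbing and sanity
  tm <- run_recovery(cfg, "tmle", n = 600L, n_reps = 6L, seed = 100L,
                     truth = truth)
  expect_equal(tm$replicates, 6L)
  expect_true(is.finite(tm$bias) && is.finite(tm$mean_se))
  expect_lt(abs(tm$bias), 0.15)  # sane scale, not a precision claim
  gc_ <- run_recovery(cfg, "gcomp", n = 600L, n_reps = 4L, seed = 100L,
                      truth = truth)
  expect_true(is.finite(gc_$bias))
})

test_that("the misspecification device omits the dominant confounder", {
  cfg <- dgp_config_dr()
  expect_equal(ancempower:::strongest_confounder(cfg), "edu")
  res <- run_double_robustness(cfg, "neither", n = 1000L, n_reps = 3L,
                               seed = 3L, truth = 0.145)
  expect_equal(res$omitted, "edu")
  expect_equal(res$tmle$replicates, 3L)
  expect_true(is.finite(res$plugin$bias))
})
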