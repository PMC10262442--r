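test_that("generation is deterministic given the seed", {
  cfg <- dgp_config(n_mothers = 300L, n_villages = 20L, seed = 77L)
  a <- generate_cohort(cfg, compute_truth = FALSE)
  b <- generate_cohort(cfg, compute_truth = FALSE)
  expect_identical(a$records, b$records)
  expect_identical(a$latent_scores, b$latent_scores)
  cfg2 <- dgp_config(n_mothers = 300L, n_villages = 20L, seed = 78L)
  expect_false(identical(generate_cohort(cfg2, compute_truth = FALSE)$records,
                         a$records))
})

test_that("generated records respect the schema invariants", {
  co <- shared_cohort()
  r <- co$records
  s <- co$config$item_schema
  for (j in 1:15) {
    expect_true(all(r[[s$item[j]]] >= 0 & r[[s$item[j]]] <= s$max_code[j]))
  }
  expect_true(all(r$cesd >= 0 & r$cesd <= 60))
  expect_true(all(r$anc_visits >= 0))
  expect_true(all(r$village_id >= 1 & r$village_id <= co$config$n_villages))
  expect_true(all(r$water %in% c(0, 1)))
})

test_that("configuration errors are rejected", {
  expect_error(dgp_config(n_mothers = 0), "positive")
  expect_error(dgp_config(n_mothers = 10, n_villages = 20), "exceed")
  expect_error(dgp_config(zero_inflation = 1.2), "zero_inflation")
  expect_error(dgp_config(missing_rates = c(edu = -0.1)), "0, 1")
  # effects so extreme the binary counterfactual means degenerate
  cfg <- dgp_config(n_mothers = 200L, effect_high = 30)
  expect_error(suppressWarnings(generate_cohort(cfg, n_mc = 1e3 * 100)),
               "outside")
})

test_that("null-effect truth is flat and default calibration holds", {
  cfg0 <- dgp_config(n_mothers = 100000L, seed = 31L,
                     effect_medium = 0, effect_high = 0)
  tr <- ancempower:::true_counterfactual_means(cfg0, n_mc = 1e5)
  for (k in rownames(tr)) {
    expect_lt(max(tr[k, ]) - min(tr[k, ]), 1e-12)
  }
  co <- generate_cohort(dgp_config(n_mothers = 100000L, seed = 32L),
                        compute_truth = FALSE)
  expect_lt(abs(mean(co$records$anc_visits) - 3.1), 0.1)
  expect_lt(abs(mean(co$records$anc_visits == 0) - 0.14), 0.02)
})

test_that("true_ate telescopes and is monotone in effect_high", {
  cfg <- dgp_config(n_mothers = 1000L, seed = 5L)
  hl <- true_ate(cfg, c("high", "low"), "count", n_mc = 1e5)
  hm <- true_ate(cfg, c("high", "medium"), "count", n_mc = 1e5)
  ml <- true_ate(cfg, c("medium", "low"), "count", n_mc = 1e5)
  expect_equal(hl, hm + ml, tolerance = 1e-12)

  prev <- -Inf
  for (eh in c(0.1, 0.25, 0.4)) {
    cur <- true_ate(dgp_config(effect_high = eh), c("high", "low"),
                    "count", n_mc = 1e5)
    expect_gt(cur, prev)
    prev <- cur
  }
  expect_error(true_ate(cfg, c("high", "low"), "count", n_mc = 10), "1e")
})

test_that("village random effects induce within-village outcome correlation", {
  icc_f <- function(village_sd, seed) {
    cfg <- dgp_config(n_mothers = 8000L, n_villages = 80L, seed = seed,
                      village_sd = village_sd)
    r <- generate_cohort(cfg, compute_truth = FALSE)$records
    fit <- stats::aov(anc_visits ~ factor(village_id), data = r)
    s <- summary(fit)[[1]]
    s$`Mean Sq`[1] / s$`Mean Sq`[2]
  }
  expect_gt(icc_f(0.5, 41L), 1.5)
  expect_lt(abs(icc_f(0, 42L) - 1), 0.25)
})

test_that("missingness injection masks covariates at the configured rates", {
  cfg <- dgp_config(n_mothers = 1609L, seed = 8L,
                    missing_rates = c(edu_diff = 0.01))
  co <- inject_missingness(generate_cohort(cfg, compute_truth = FALSE), cfg)
  n_miss <- sum(is.na(co$records$edu_diff))
  # binomial(1609, 0.01): expectation 16.1, assert within 4 SD (~5.1)
  expect_lt(abs(n_miss - 16.1), 4 * sqrt(1609 * 0.01 * 0.99))
  expect_false(anyNA(co$records$anc_visits))
  expect_false(anyNA(co$records$village_id))

  cfg0 <- dgp_config(n_mothers = 200L, seed = 9L, missing_rates = numeric(0))
  co0 <- generate_cohort(cfg0, compute_truth = FALSE)
  expect_identical(inject_missingness(co0, cfg0)$records, co0$records)

  cfg1 <- dgp_config(n_mothers = 200L, seed = 9L, missing_rates = c(cesd = 1))
  co1 <- inject_missingness(generate_cohort(cfg1, compute_truth = FALSE), cfg1)
  expect_true(all(is.na(co1$records$cesd)))
  expect_error(
    inject_missingness(co1, dgp_config(n_mothers = 200L,
                                       missing_rates = c(anc_visits = 0.1))),
    "cannot mask"
  )
})

test_that("cohorts round-trip through CSV with a JSON sidecar", {
  cfg <- dgp_config(n_mothers = 150L, n_villages = 10L, seed = 12L)
  co <- generate_cohort(cfg, n_mc = 1e5)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_cohort(co, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 150L)
  expect_equal(back$anc_visits, co$records$anc_visits)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(side$config$seed, 12L)
  cnt <- side$truth[side$truth$spec == "count", c("low", "medium", "high")]
  expect_equal(unname(unlist(cnt)), unname(co$truth["count", ]),
               tolerance = 1e-9)
})
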