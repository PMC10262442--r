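sim_binary <- function(n, p = 8, sparse = TRUE, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- if (sparse) c(1.5, -1, 0.8, rep(0, p - 3)) else rnorm(p, 0, 0.5)
  y <- rbinom(n, 1, plogis(x %*% beta))
  list(x = x, y = y)
}

test_that("a single-learner library gets weight one", {
  d <- sim_binary(300)
  sl <- fit_super_learner(d$x, d$y, learner_library("glm"), n_folds = 5,
                          loss = "nll", seed = 3)
  expect_equal(unname(sl$weights), 1)
  expect_true(is.finite(sl$cv_risk[["glm"]]))
  # cv = FALSE shortcut also yields weight one
  sl2 <- fit_super_learner(d$x, d$y, learner_library("glm"), loss = "nll",
                           seed = 3, cv = FALSE)
  expect_equal(unname(sl2$weights), 1)
})

test_that("the convex ensemble never does worse than its best vertex", {
  d <- sim_binary(400, seed = 5)
  sl <- fit_super_learner(d$x, d$y,
                          learner_library(c("glm", "lasso", "ridge")),
                          n_folds = 5, loss = "nll", seed = 11)
  expect_true(all(sl$weights >= 0))
  expect_equal(sum(sl$weights), 1, tolerance = 1e-12)
  expect_lte(sl$cv_risk_ensemble, min(sl$cv_risk) + 1e-8)

  # continuous loss
  set.seed(6)
  x <- matrix(rnorm(300 * 5), 300, 5)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(300)
  slc <- fit_super_learner(x, y, learner_library(c("glm", "ridge")),
                           n_folds = 5, loss = "mse", seed = 12)
  expect_lte(slc$cv_risk_ensemble, min(slc$cv_risk) + 1e-8)
})

test_that("penalized-linear learners dominate on a sparse logistic truth", {
  d <- sim_binary(2000, p = 12, sparse = TRUE, seed = 9)
  sl <- fit_super_learner(d$x, d$y,
                          learner_library(c("lasso", "enet", "random_forest")),
                          n_folds = 5, loss = "nll", seed = 21)
  penalized <- sum(sl$weights[c("lasso", "enet")])
  expect_gt(penalized, 0.5)
})

test_that("deterministic learners give order-invariant predictions", {
  d <- sim_binary(250, seed = 13)
  lib <- learner_library("glm")
  sl1 <- fit_super_learner(d$x, d$y, lib, n_folds = 5, loss = "nll", seed = 2)
  perm <- sample(nrow(d$x))
  sl2 <- fit_super_learner(d$x[perm, ], d$y[perm], lib, n_folds = 5,
                           loss = "nll", seed = 2)
  newx <- matrix(rnorm(20 * ncol(d$x)), 20)
  expect_equal(sl1$predict(newx), sl2$predict(newx), tolerance = 1e-10)
})

test_that("failing learners are dropped; an empty fit errors", {
  broken <- ancempower:::new_learner("broken", function(x, y, family) {
    stop("refuses to fit")
  })
  d <- sim_binary(200, seed = 17)
  expect_warning(
    sl <- fit_super_learner(d$x, d$y, c(learner_library("glm"), list(broken)),
                            n_folds = 4, loss = "nll", seed = 4),
    "dropped"
  )
  expect_equal(unname(sl$weights), 1)
  expect_error(
    suppressWarnings(fit_super_learner(d$x, d$y, list(broken), n_folds = 4,
                                       loss = "nll", seed = 4)),
    "all base learners failed"
  )
})
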