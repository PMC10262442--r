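# Base learners for the Super Learner library.
#
# A learner is a list(name, fit) where fit(x, y, family) returns an object
# with a $predict(newx) closure producing probabilities (binomial) or
# conditional means (gaussian). x is a numeric matrix. Learners are
# deterministic given the RNG state at fit time.

new_learner <- function(name, fit) {
  structure(list(name = name, fit = fit), class = "learner")
}

#' Base learner constructors
#'
#' Constructors for the prediction algorithms available to the Super
#' Learner library: plain linear/logistic regression, a Bayesian-regularized
#' (Gaussian-prior MAP, i.e. fixed small ridge penalty) logistic regression,
#' LASSO / ridge / elastic net with internal cross-validated penalty
#' selection, random forest, gradient-boosted trees, and a spline-basis
#' LASSO: an L1-penalized fit on zero-order indicator bases over per-column
#' quantile knots (a desk-scale surrogate for the highly adaptive LASSO,
#' with a capped basis size).
#'
#' @param alpha elastic-net mixing parameter for [lrnr_enet()].
#' @param num_trees,mtry random-forest size parameters.
#' @param nrounds,max_depth,eta boosting parameters.
#' @param n_knots quantile knots per column for the spline-basis LASSO.
#' @param max_basis cap on the number of generated basis columns.
#' @param prior_sd Gaussian prior SD for the Bayesian-regularized logistic.
#' @return a `learner` object with a `fit(x, y, family)` entry.
#' @name learners
NULL

glmnet_predict <- function(fit, newx, s) {
  as.numeric(stats::predict(fit, newx = newx, s = s, type = "response"))
}

#' @rdname learners
#' @export
lrnr_glm <- function() {
  new_learner("glm", function(x, y, family) {
    # prune linearly dependent columns so the fit is full rank and
    # prediction is well defined on any new data
    x <- as.matrix(x)
    qx <- qr(cbind(1, x))
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    keep <- setdiff(keep, 1L) - 1L
    df <- data.frame(y = y, x[, keep, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = family))
    list(predict = function(newx) {
      nd <- data.frame(as.matrix(newx)[, keep, drop = FALSE])
      names(nd) <- names(df)[-1]
      as.numeric(stats::predict(fit, newdata = nd, type = "response"))
    })
  })
}

#' @rdname learners
#' @export
lrnr_bayes_glm <- function(prior_sd = 2.5) {
  new_learner("bayes_glm", function(x, y, family) {
    # MAP under independent Gaussian coefficient priors = ridge with fixed
    # penalty lambda = 1 / (n * prior_sd^2)
    lam <- 1 / (length(y) * prior_sd^2)
    fit <- glmnet::glmnet(x, y, family = family, alpha = 0,
                          lambda = c(lam * 10, lam))
    list(predict = function(newx) glmnet_predict(fit, newx, lam))
  })
}

cv_glmnet_learner <- function(name, alpha) {
  new_learner(name, function(x, y, family) {
    fit <- glmnet::cv.glmnet(x, y, family = family, alpha = alpha, nfolds = 5)
    list(predict = function(newx) glmnet_predict(fit, newx, "lambda.min"))
  })
}

#' @rdname learners
#' @export
lrnr_lasso <- function() cv_glmnet_learner("lasso", 1)

#' @rdname learners
#' @export
lrnr_ridge <- function() cv_glmnet_learner("ridge", 0)

#' @rdname learners
#' @export
lrnr_enet <- function(alpha = 0.5) cv_glmnet_learner("enet", alpha)

#' @rdname learners
#' @export
lrnr_random_forest <- function(num_trees = 200, mtry = NULL) {
  new_learner("random_forest", function(x, y, family) {
    df <- data.frame(x)
    binary <- identical(family, "binomial")
    yy <- if (binary) factor(y, levels = c(0, 1)) else y
    fit <- ranger::ranger(x = df, y = yy, num.trees = num_trees, mtry = mtry,
                          probability = binary, num.threads = 1,
                          respect.unordered.factors = TRUE)
    list(predict = function(newx) {
      p <- stats::predict(fit, data = data.frame(newx),
                          num.threads = 1)$predictions
      if (binary) as.numeric(p[, "1"]) else as.numeric(p)
    })
  })
}

#' @rdname learners
#' @export
lrnr_xgboost <- function(nrounds = 60, max_depth = 3, eta = 0.2) {
  new_learner("xgboost", function(x, y, family) {
    obj <- if (identical(family, "binomial")) "binary:logistic" else "reg:squarederror"
    fit <- xgboost::xgb.train(
      params = list(objective = obj, max_depth = max_depth, eta = eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    list(predict = function(newx) {
      as.numeric(stats::predict(
        fit, xgboost::xgb.DMatrix(as.matrix(newx), nthread = 1)))
    })
  })
}

# Zero-order indicator basis over per-column quantile knots (main terms
# plus a capped set of two-way interaction indicators).
hal_basis <- function(x, knots) {
  cols <- list()
  for (j in seq_len(ncol(x))) {
    for (k in knots[[j]]) {
      cols[[length(cols) + 1L]] <- as.numeric(x[, j] >= k)
    }
  }
  b <- do.call(cbind, cols)
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  b
}

#' @rdname learners
#' @export
lrnr_hal_surrogate <- function(n_knots = 5, max_basis = 300) {
  new_learner("spline_lasso", function(x, y, family) {
    knots <- lapply(seq_len(ncol(x)), function(j) {
      u <- unique(stats::quantile(x[, j], probs = seq(0.1, 0.9,
                                                      length.out = n_knots),
                                  names = FALSE, type = 7))
      u[seq_len(min(length(u), n_knots))]
    })
    b <- hal_basis(x, knots)
    if (ncol(b) > max_basis) b <- b[, seq_len(max_basis), drop = FALSE]
    keep <- apply(b, 2, stats::sd) > 0
    b <- b[, keep, drop = FALSE]
    if (ncol(b) < 2L) {
      # degenerate design: fall back to the intercept-only mean
      mu <- mean(y)
      return(list(predict = function(newx) rep(mu, nrow(newx))))
    }
    fit <- glmnet::cv.glmnet(b, y, family = family, alpha = 1, nfolds = 5)
    list(predict = function(newx) {
      nb <- hal_basis(newx, knots)[, which(keep), drop = FALSE]
      glmnet_predict(fit, nb, "lambda.min")
    })
  })
}

#' @rdname learners
#' @param names character vector of learner names to assemble a library.
#' @export
learner_library <- function(names = c("glm", "lasso", "ridge")) {
  constructors <- list(
    glm = lrnr_glm, bayes_glm = lrnr_bayes_glm, lasso = lrnr_lasso,
    ridge = lrnr_ridge, enet = lrnr_enet,
    random_forest = lrnr_random_forest, xgboost = lrnr_xgboost,
    spline_lasso = lrnr_hal_surrogate
  )
  unknown <- setdiff(names, names(constructors))
  if (length(unknown) > 0) {
    stop(sprintf("unknown learners: %s", paste(unknown, collapse = ", ")))
  }
  lapply(names, function(nm) constructors[[nm]]())
}
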