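#' Fit a convex Super Learner
#'
#' Cross-validation-based stacking: each base learner produces V-fold
#' out-of-fold predictions; meta-weights on the probability simplex are
#' chosen to minimize the cross-validated loss of the convex combination
#' (negative Bernoulli log-likelihood for binary targets, squared error for
#' continuous ones); the base learners are then refit on all data. Because
#' the simplex contains every vertex, the ensemble's cross-validated loss
#' never exceeds the best single learner's (the optimizer result is
#' compared against every vertex and the better of the two is kept).
#'
#' @param x numeric feature matrix.
#' @param y target vector (0/1 for binary loss).
#' @param library list of learners from [learner_library()].
#' @param n_folds number of cross-validation folds (>= 2; default 10,
#'   stratified by the target for binary losses).
#' @param loss `"nll"` (binary) or `"mse"` (continuous).
#' @param seed integer seed controlling fold assignment and stochastic
#'   learners.
#' @param cv if `FALSE` and the library has a single learner, skip
#'   cross-validation and assign it weight 1 (used in replicated
#'   simulations).
#' @return object of class `super_learner`: `weights`, `cv_risk` (named
#'   per-learner CV losses), `cv_risk_ensemble`, `folds`, `loss`, and a
#'   `predict(newx)` closure.
#' @export
fit_super_learner <- function(x, y, library, n_folds = 10, loss = c("nll", "mse"),
                              seed = 1L, cv = TRUE) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  if (length(library) == 0) stop("learner library must be nonempty")
  if (n_folds < 2) stop("n_folds must be at least 2")
  family <- if (loss == "nll") "binomial" else "gaussian"
  set.seed(seed)

  fit_all <- function(lib) {
    fits <- vector("list", length(lib))
    ok <- logical(length(lib))
    for (k in seq_along(lib)) {
      f <- tryCatch(lib[[k]]$fit(x, y, family), error = function(e) {
        warning(sprintf("learner '%s' failed to fit: %s",
                        lib[[k]]$name, conditionMessage(e)))
        NULL
      })
      fits[k] <- list(f)
      ok[k] <- !is.null(f)
    }
    list(fits = fits, ok = ok)
  }

  if (!cv && length(library) == 1L) {
    full <- fit_all(library)
    if (!any(full$ok)) stop("all base learners failed to fit")
    fit1 <- full$fits[[1]]
    out <- list(
      learner_names = library[[1]]$name, weights = 1,
      cv_risk = stats::setNames(NA_real_, library[[1]]$name),
      cv_risk_ensemble = NA_real_, folds = NULL, loss = loss,
      predict = function(newx) fit1$predict(as.matrix(newx))
    )
    class(out) <- "super_learner"
    return(out)
  }

  folds <- make_folds(y, n_folds, stratify = (loss == "nll"))
  n <- length(y)
  K <- length(library)
  z <- matrix(NA_real_, n, K)
  failed <- logical(K)
  for (k in seq_len(K)) {
    preds <- rep(NA_real_, n)
    bad <- FALSE
    for (v in seq_len(n_folds)) {
      test_idx <- which(folds == v)
      train_idx <- setdiff(seq_len(n), test_idx)
      f <- tryCatch(
        library[[k]]$fit(x[train_idx, , drop = FALSE], y[train_idx], family),
        error = function(e) NULL
      )
      if (is.null(f)) { bad <- TRUE; break }
      preds[test_idx] <- f$predict(x[test_idx, , drop = FALSE])
    }
    if (bad || anyNA(preds)) {
      warning(sprintf("learner '%s' dropped (cross-validation failure)",
                      library[[k]]$name))
      failed[k] <- TRUE
    } else {
      z[, k] <- preds
    }
  }
  keep <- which(!failed)
  if (length(keep) == 0) stop("all base learners failed to fit")
  z <- z[, keep, drop = FALSE]

  risk <- function(p) {
    if (loss == "nll") {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    } else {
      mean((y - p)^2)
    }
  }
  vertex_risks <- apply(z, 2, risk)
  weights <- solve_simplex_weights(z, risk, vertex_risks)
  ens_risk <- risk(as.numeric(z %*% weights))

  full <- fit_all(library[keep])
  fits <- full$fits
  ok <- full$ok
  if (!all(ok)) {
    weights <- weights * ok
    if (sum(weights) == 0) stop("all base learners failed on the full data")
    weights <- weights / sum(weights)
  }
  nm <- vapply(library[keep], function(l) l$name, character(1))
  predict_fun <- function(newx) {
    newx <- as.matrix(newx)
    p <- matrix(0, nrow(newx), length(fits))
    for (k in seq_along(fits)) {
      if (weights[k] > 0) p[, k] <- fits[[k]]$predict(newx)
    }
    as.numeric(p %*% weights)
  }
  out <- list(
    learner_names = nm, weights = stats::setNames(weights, nm),
    cv_risk = stats::setNames(vertex_risks, nm), cv_risk_ensemble = ens_risk,
    folds = folds, loss = loss, predict = predict_fun
  )
  class(out) <- "super_learner"
  out
}

# V-fold assignment, optionally stratified by a binary target.
make_folds <- function(y, n_folds, stratify = FALSE) {
  n <- length(y)
  folds <- integer(n)
  assign_block <- function(idx) {
    rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
  }
  if (stratify && length(unique(y)) == 2L) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- assign_block(idx)
    }
  } else {
    folds <- assign_block(seq_len(n))
  }
  folds
}

# Minimize risk(z %*% w) over the probability simplex. Softmax
# reparametrization optimized from several starts; the best vertex is a
# fallback candidate so the returned weights never do worse than any
# single learner on the CV objective.
solve_simplex_weights <- function(z, risk, vertex_risks) {
  K <- ncol(z)
  if (K == 1L) return(1)
  softmax <- function(theta) {
    e <- exp(theta - max(theta))
    e / sum(e)
  }
  obj <- function(theta) risk(as.numeric(z %*% softmax(theta)))
  starts <- list(rep(0, K))
  best_v <- which.min(vertex_risks)
  tilted <- rep(-2, K); tilted[best_v] <- 2
  starts[[2]] <- tilted
  best_w <- NULL
  best_r <- Inf
  for (s in starts) {
    opt <- tryCatch(stats::optim(s, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(opt) && opt$value < best_r) {
      best_r <- opt$value
      best_w <- softmax(opt$par)
    }
  }
  # vertex fallback: the simplex contains every vertex, so never return a
  # combination worse than the best single learner
  if (is.null(best_w) || min(vertex_risks) < best_r) {
    best_w <- rep(0, K)
    best_w[best_v] <- 1
  }
  best_w / sum(best_w)
}
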