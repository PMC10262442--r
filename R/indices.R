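#' WEAI-style aggregate empowerment score
#'
#' Computes the equal-domain-weight empowerment score from 15 ordinal item
#' responses. Items are summed within each domain; each domain sum is divided
#' by its maximum attainable sum, the three domain proportions are averaged
#' with equal weight, and the result is rescaled to 0-100. All-maximum
#' responses therefore score exactly 100 and all-minimum exactly 0.
#'
#' @param item_responses matrix or data.frame, one row per respondent,
#'   15 columns of integer codes (0 = least empowered).
#' @param schema an [item_schema()].
#' @return list of class `empowerment_scores` with components
#'   `aggregate` (numeric in \[0, 100\]), `decision`, `movement`, `assets`
#'   (raw per-domain sums), and `domain_max` (named maxima).
#' @export
score_weai <- function(item_responses, schema = item_schema()) {
  responses <- validate_item_responses(item_responses, schema)
  domains <- c("decision", "movement", "assets")
  sums <- lapply(domains, function(d) {
    cols <- domain_columns(schema, d)
    as.numeric(rowSums(responses[, cols, drop = FALSE]))
  })
  names(sums) <- domains
  maxima <- vapply(domains, function(d) {
    sum(schema$max_code[domain_columns(schema, d)])
  }, numeric(1))
  props <- mapply(function(s, m) s / m, sums, maxima)
  props <- matrix(props, ncol = 3L)
  out <- list(
    aggregate = 100 * rowMeans(props),
    decision = sums$decision,
    movement = sums$movement,
    assets = sums$assets,
    domain_max = maxima
  )
  class(out) <- "empowerment_scores"
  out
}

#' Categorize a score into low / medium / high by sample quantiles
#'
#' Low is strictly below the lower quantile cutpoint, high is at or above the
#' upper cutpoint, medium is everything in between. Defaults reproduce a
#' bottom-25% / middle-50% / top-25% split; ties at a cutpoint go to the
#' higher category. Cutpoints are linear-interpolation sample quantiles
#' (`stats::quantile`, type 7).
#'
#' @param scores numeric vector (at least 4 distinct values).
#' @param lower,upper quantile probabilities for the cutpoints.
#' @return list with `category` (factor low/medium/high), `cutpoints`
#'   (named numeric length 2), and `shares` (realized category proportions).
#' @export
categorize_quantile <- function(scores, lower = 0.25, upper = 0.75) {
  if (anyNA(scores)) stop("scores must be complete")
  if (length(scores) < 4L) {
    stop("need at least 4 observations to form quantile categories")
  }
  if (length(unique(scores)) < 2L) {
    stop("scores are constant; no variation to categorize")
  }
  cuts <- stats::quantile(scores, probs = c(lower, upper), names = FALSE, type = 7)
  category <- factor(
    ifelse(scores < cuts[1], "low", ifelse(scores >= cuts[2], "high", "medium")),
    levels = c("low", "medium", "high")
  )
  list(
    category = category,
    cutpoints = stats::setNames(cuts, c("lower", "upper")),
    shares = as.numeric(prop.table(table(category)))
  )
}

#' SWPER-style principal-component empowerment indices
#'
#' Standardizes the 15 items and eigendecomposes their correlation matrix,
#' keeping the first three components (intended to track decision-making
#' power, freedom of movement and control over assets). Each retained
#' component is sign-aligned so it correlates positively with the WEAI-style
#' subscale it most strongly tracks (largest absolute correlation).
#'
#' @param item_matrix matrix/data.frame of 15 ordinal item columns, complete
#'   rows only, at least 15 rows.
#' @param schema an [item_schema()].
#' @return list of class `pca_indices`: `scores` (n x 3 matrix), `loadings`
#'   (items x 3), `var_explained` (length 3, non-increasing), `sign_flipped`
#'   (logical 3), `matched_subscale` (character 3), `dropped_items`
#'   (character, zero-variance items excluded with a warning).
#' @export
score_swper_pca <- function(item_matrix, schema = item_schema()) {
  responses <- validate_item_responses(item_matrix, schema)
  if (nrow(responses) < 15L) stop("need at least 15 complete rows for PCA")
  sds <- apply(responses, 2, stats::sd)
  dropped <- colnames(responses)[sds == 0]
  if (is.null(colnames(responses))) {
    colnames(responses) <- schema$item
    dropped <- schema$item[sds == 0]
  }
  if (length(dropped) > 0) {
    warning(sprintf("dropping zero-variance items: %s",
                    paste(dropped, collapse = ", ")))
  }
  keep <- sds > 0
  x <- scale(responses[, keep, drop = FALSE])
  if (ncol(x) < 3L) stop("fewer than 3 items with variance; PCA indices undefined")
  eig <- eigen(stats::cor(responses[, keep, drop = FALSE]), symmetric = TRUE)
  load <- eig$vectors[, 1:3, drop = FALSE]
  scores <- x %*% load
  var_explained <- eig$values[1:3] / sum(eig$values)

  weai <- score_weai(responses, schema)
  subscales <- cbind(decision = weai$decision, movement = weai$movement,
                     assets = weai$assets)
  matched <- character(3)
  flipped <- logical(3)
  for (k in 1:3) {
    cors <- suppressWarnings(stats::cor(scores[, k], subscales))
    cors[is.na(cors)] <- 0
    m <- which.max(abs(cors))
    matched[k] <- colnames(subscales)[m]
    if (cors[m] < 0) {
      scores[, k] <- -scores[, k]
      load[, k] <- -load[, k]
      flipped[k] <- TRUE
    }
  }
  rownames(load) <- colnames(responses)[keep]
  colnames(load) <- colnames(scores) <- paste0("PC", 1:3)
  out <- list(scores = scores, loadings = load, var_explained = var_explained,
              sign_flipped = flipped, matched_subscale = matched,
              dropped_items = dropped)
  class(out) <- "pca_indices"
  out
}

#' WAMI socioeconomic index (0-32)
#'
#' Sums four equally weighted components, each worth 0-8 points: improved
#' water/sanitation (4 points per binary indicator), assets (1 point per
#' owned asset out of 8), maternal education (years, capped at 8 points by
#' default), and monthly household income (mapped to 0-8 by configurable
#' band breaks). Households are categorized by the fixed published cutoffs:
#' high >= 21, medium >= 17 and < 21, low < 17.
#'
#' @param water,sanitation 0/1 vectors (improved source indicators).
#' @param assets matrix/data.frame with 8 binary asset-ownership columns.
#' @param education maternal education in completed years (nonnegative).
#' @param income monthly household income (nonnegative, e.g. USD).
#' @param weights named list of per-component maxima; default gives each
#'   component 8 points (total 32).
#' @param income_breaks increasing numeric breaks mapping income to points
#'   0..8 (income < breaks\[1\] scores 0, >= breaks\[8\] scores 8).
#' @param education_cap years at or above which the education component is
#'   maximal.
#' @return list of class `wami_score` with `score` (0-32) and `category`
#'   (factor low/medium/high).
#' @export
score_wami <- function(water, sanitation, assets, education, income,
                       weights = list(water_san = 8, assets = 8,
                                      education = 8, income = 8),
                       income_breaks = c(25, 50, 75, 100, 150, 200, 300, 400),
                       education_cap = 8) {
  assets <- as.matrix(assets)
  if (ncol(assets) != 8L) stop("expected 8 asset indicator columns")
  chk01 <- function(x, what) {
    if (any(!x %in% c(0, 1))) stop(sprintf("%s must be binary 0/1", what))
  }
  chk01(water, "water"); chk01(sanitation, "sanitation"); chk01(assets, "assets")
  if (any(education < 0) || any(income < 0)) {
    stop("education and income must be nonnegative")
  }
  if (length(income_breaks) != 8L || is.unsorted(income_breaks, strictly = TRUE)) {
    stop("income_breaks must be 8 strictly increasing values")
  }
  water_san <- (water + sanitation) / 2 * weights$water_san
  asset_pts <- rowSums(assets) / 8 * weights$assets
  edu_pts <- pmin(education / education_cap, 1) * weights$education
  income_pts <- rowSums(outer(income, income_breaks, ">=")) / 8 * weights$income
  score <- water_san + asset_pts + edu_pts + income_pts
  category <- factor(
    ifelse(score >= 21, "high", ifelse(score >= 17, "medium", "low")),
    levels = c("low", "medium", "high")
  )
  out <- list(score = as.numeric(score), category = category)
  class(out) <- "wami_score"
  out
}

#' Household wealth index: first principal component of asset indicators
#'
#' Returns the leading principal component of the asset-ownership matrix,
#' zero-centered and oriented so that owning more assets increases the
#' score.
#'
#' @param asset_indicators matrix/data.frame of binary (or ordinal) asset
#'   columns; at least 2 columns with variation.
#' @return numeric vector of component scores (mean 0).
#' @export
wealth_pca <- function(asset_indicators) {
  x <- as.matrix(asset_indicators)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 asset columns with variation")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  total <- rowSums(asset_indicators)
  if (stats::sd(total) > 0 && stats::cor(scores, total) < 0) scores <- -scores
  as.numeric(scores - mean(scores))
}
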