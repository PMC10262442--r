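test_that("WEAI-style aggregate hits its bounds and equal-weight identity", {
  s <- item_schema()
  resp_max <- matrix(rep(s$max_code, each = 2), nrow = 2)
  resp_min <- matrix(0L, nrow = 2, ncol = 15)
  expect_equal(score_weai(resp_max, s)$aggregate, c(100, 100))
  expect_equal(score_weai(resp_min, s)$aggregate, c(0, 0))

  # only the decision domain at maximum: 100 * (1 + 0 + 0) / 3
  resp <- matrix(0L, nrow = 1, ncol = 15)
  resp[1, 1:7] <- s$max_code[1:7]
  expect_equal(score_weai(resp, s)$aggregate, 100 / 3)

  # mixed level counts keep the bounds
  s2 <- item_schema(c(rep(2L, 7), rep(5L, 3), rep(4L, 5)))
  expect_equal(score_weai(matrix(rep(s2$max_code, each = 1), 1), s2)$aggregate, 100)
})

test_that("raising any single item never decreases the aggregate", {
  s <- item_schema()
  set.seed(7)
  for (rep in 1:20) {
    resp <- vapply(s$max_code, function(m) sample(0:m, 1), integer(1))
    j <- sample(15, 1)
    if (resp[j] == s$max_code[j]) next
    bumped <- resp
    bumped[j] <- bumped[j] + 1L
    expect_gte(score_weai(matrix(bumped, 1), s)$aggregate,
               score_weai(matrix(resp, 1), s)$aggregate)
  }
})

test_that("invalid responses are rejected with the item index", {
  s <- item_schema()
  bad <- matrix(0L, 1, 15)
  bad[1, 9] <- 5L
  expect_error(score_weai(bad, s), "item 9")
  expect_error(item_schema(rep(3L, 14)), "15 items")
  expect_error(item_schema(c(1L, rep(3L, 14))), "at least 2")
})

test_that("quantile categorization gives 25/50/25 on distinct scores", {
  res <- categorize_quantile(1:100)
  expect_equal(as.integer(table(res$category)), c(25, 50, 25))
  expect_equal(res$shares, c(0.25, 0.50, 0.25))
})

test_that("ties at a cutpoint follow the >=/< rule (hand-enumerated)", {
  # sorted: 1, 5 x9, 9, 9; both type-7 cutpoints land on 5, so by the
  # rule low = {1}, high = the nine 5s and two 9s, medium empty
  scores <- c(1, rep(5, 9), 9, 9)
  res <- categorize_quantile(scores)
  expect_equal(unname(res$cutpoints), c(5, 5))
  expect_equal(as.integer(table(res$category)), c(1, 0, 11))
})

test_that("degenerate score vectors are rejected", {
  expect_error(categorize_quantile(rep(3, 10)), "constant")
  expect_error(categorize_quantile(c(1, 2, 3)), "4 observations")
})

test_that("WAMI scoring matches the printed scale and cutoffs", {
  # all components maximal -> 32
  max_score <- score_wami(1, 1, matrix(1, 1, 8), 8, 500)
  expect_equal(max_score$score, 32)
  expect_equal(as.character(max_score$category), "high")
  # all minimal -> 0
  expect_equal(score_wami(0, 0, matrix(0, 1, 8), 0, 0)$score, 0)
  # fixed cutoffs: 17 medium, 21 high, 16.9 low
  base <- function(edu) score_wami(1, 1, matrix(1, 1, 8), edu, 0)
  expect_equal(base(1)$score, 17)
  expect_equal(as.character(base(1)$category), "medium")
  expect_equal(base(5)$score, 21)
  expect_equal(as.character(base(5)$category), "high")
  expect_equal(base(0.9)$score, 16.9)
  expect_equal(as.character(base(0.9)$category), "low")
  expect_error(score_wami(2, 0, matrix(0, 1, 8), 0, 0), "binary")
})

test_that("wealth PCA recovers a dominant ownership gradient", {
  set.seed(11)
  n <- 600
  z <- rnorm(n)
  assets <- vapply(seq(-1.5, 1.5, length.out = 10), function(a) {
    rbinom(n, 1, plogis(a + 2 * z))
  }, numeric(n))
  pc <- wealth_pca(assets)
  expect_gt(cor(pc, z), 0.9)
  expect_lt(abs(mean(pc)), 1e-10)
  expect_gt(cor(pc, rowSums(assets)), 0)
  expect_error(wealth_pca(matrix(1, 10, 3)), "variation")
})

test_that("PCA indices recover block structure and are sign-aligned", {
  set.seed(21)
  n <- 800
  s <- item_schema()
  lat <- matrix(rnorm(n * 3), n, 3)
  blocks <- list(1:7, 8:10, 11:15)
  items <- matrix(0L, n, 15)
  for (b in 1:3) {
    for (j in blocks[[b]]) {
      items[, j] <- as.integer(cut(lat[, b] + rnorm(n, 0, 0.5),
                                   c(-Inf, -0.6, 0.6, Inf))) - 1L
    }
  }
  res <- score_swper_pca(items, s)
  # variance explained non-increasing
  expect_true(all(diff(res$var_explained) <= 1e-12))
  # each component loads predominantly on one block
  for (k in 1:3) {
    block_load <- vapply(blocks, function(b) mean(abs(res$loadings[b, k])),
                         numeric(1))
    top_block <- which.max(block_load)
    expect_gt(block_load[top_block], max(block_load[-top_block]))
  }
  # sign alignment with the matched WEAI subscale
  weai <- score_weai(items, s)
  subs <- cbind(decision = weai$decision, movement = weai$movement,
                assets = weai$assets)
  for (k in 1:3) {
    expect_gt(cor(res$scores[, k], subs[, res$matched_subscale[k]]), 0)
  }
  # component scores pairwise uncorrelated
  cc <- cor(res$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # duplicating every row leaves loadings unchanged
  res2 <- score_swper_pca(items[rep(seq_len(n), 2), ], s)
  expect_equal(res2$loadings, res$loadings, tolerance = 1e-8)
})

test_that("zero-variance items are dropped with a warning", {
  set.seed(3)
  items <- matrix(sample(0:2, 40 * 15, replace = TRUE), 40, 15)
  items[, 4] <- 1L
  expect_warning(res <- score_swper_pca(items), "zero-variance")
  expect_equal(res$dropped_items, "item_4")
})
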