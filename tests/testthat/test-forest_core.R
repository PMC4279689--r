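test_that("compute_mtry follows the first-integer-greater-than-p/3 rule", {
  expect_identical(compute_mtry(10), 4L)
  expect_identical(compute_mtry(2), 1L)
  expect_identical(compute_mtry(3), 2L)   # strict reading at a multiple of 3
  expect_identical(compute_mtry(3, rule = "ceiling"), 1L)
  expect_error(compute_mtry(0), "positive")

  # oracle: smallest integer strictly greater than p/3, clamped to [1, p]
  for (p in 1:40) {
    z <- p / 3
    m <- 1L
    while (m <= z) m <- m + 1L
    expect_identical(compute_mtry(p), max(1L, min(p, m)))
  }
})

test_that("seeded fits are exactly reproducible and validate inputs", {
  d <- make_toy_regression()
  f1 <- grow_forest(d, ntree = 30, seed = 9)
  f2 <- grow_forest(d, ntree = 30, seed = 9)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  expect_identical(f1$inbag, f2$inbag)
  f3 <- grow_forest(d, ntree = 30, seed = 10)
  expect_false(identical(predict(f1, d$X), predict(f3, d$X)))

  expect_error(grow_forest(d, nodesize = d$n + 1), "nodesize")
  expect_error(grow_forest(d, mtry = d$p + 1), "mtry")
  expect_error(sf_dataset(matrix(c(1, NA, 3, 4), 2), c(1, 2), "regression"),
               "missing")
  expect_error(predict(f1, d$X[, 1:2]), "columns")
})

test_that("bootstrap rows sum to n and predictions are convex in y", {
  d <- make_toy_regression(n = 70)
  f <- grow_forest(d, ntree = 40, nodesize = 3, seed = 2)
  expect_true(all(rowSums(f$inbag) == d$n))

  set.seed(5)
  Xnew <- matrix(runif(200 * d$p), 200)
  pred <- predict(f, Xnew)
  expect_true(all(pred >= min(d$y) & pred <= max(d$y)))
})

test_that("nodesize = n collapses every tree to its bootstrap mean", {
  d <- make_toy_regression(n = 50)
  f <- grow_forest(d, ntree = 20, nodesize = d$n, seed = 3)
  bytree <- predict(f, d$X, bytree = TRUE)
  # each tree predicts one constant: the inbag-weighted outcome mean
  for (t in 1:20) {
    expect_equal(unique(bytree[, t]),
                 sum(f$inbag[t, ] * d$y) / d$n, tolerance = 1e-12)
  }
  pred <- predict(f, d$X)
  expect_equal(max(pred) - min(pred), 0)
  expect_lt(abs(pred[1] - mean(d$y)), 5 * stats::sd(d$y) / sqrt(d$n * 20))
})

test_that("single-tree predictions match an R node-traversal oracle", {
  for (seed in c(4, 11)) {
    d <- make_toy_regression(n = 60, seed = seed)
    f <- grow_forest(d, ntree = 1, nodesize = 5, seed = seed)
    tree <- f$trees[[1]]
    set.seed(seed + 1)
    Xnew <- rbind(d$X, matrix(runif(40 * d$p), 40))
    expect_equal(predict(f, Xnew), tree$value[r_tree_leaves(tree, Xnew)],
                 tolerance = 1e-12)
    # leaf values are the bootstrap means of the cases routed to that leaf
    leaves <- r_tree_leaves(tree, d$X)
    w <- f$inbag[1, ]
    for (L in unique(leaves[w > 0])) {
      in_leaf <- leaves == L & w > 0
      expect_equal(tree$value[L],
                   sum(w[in_leaf] * d$y[in_leaf]) / sum(w[in_leaf]),
                   tolerance = 1e-12)
    }
    # splittability rule: terminal nodes hold < 2 * nodesize bootstrap cases
    expect_true(all(tapply(w[w > 0], leaves[w > 0], sum) < 10))
  }
})

test_that("multiclass probabilities are row-stochastic", {
  d <- make_toy_multiclass()
  f <- grow_forest(d, ntree = 40, seed = 6)
  pr <- predict(f, d$X)
  expect_equal(dim(pr), c(d$n, d$J))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, d$n), tolerance = 1e-12)
})

test_that("OOB aggregation uses only trees that excluded the case", {
  d <- make_toy_regression(n = 40)
  f <- grow_forest(d, ntree = 12, nodesize = 4, seed = 7)
  oob <- oob_predict(f, d)
  bytree <- predict(f, d$X, bytree = TRUE)
  for (i in seq_len(d$n)) {
    out <- f$inbag[, i] == 0
    if (any(out)) {
      expect_true(oob$covered[i])
      expect_equal(oob$values[i], mean(bytree[i, out]), tolerance = 1e-12)
    } else {
      expect_false(oob$covered[i])
      expect_true(is.na(oob$values[i]))
    }
  }
  # imputation fills uncovered cases with the full-forest prediction
  oob2 <- oob_predict(f, d, impute_uncovered = TRUE)
  expect_false(anyNA(oob2$values))
})

test_that("single-bootstrap OOB coverage is near 1/e and large ntree covers all", {
  n <- 1000
  d <- sf_dataset(matrix(runif(n)), rnorm(n), "regression")
  cover <- vapply(1:20, function(s) {
    mean(!grow_forest(d, ntree = 1, nodesize = n, mtry = 1, seed = s)$inbag[1, ] > 0)
  }, numeric(1))
  expect_lt(abs(mean(cover) - exp(-1)), 0.01)

  d2 <- make_toy_regression(n = 100)
  f <- grow_forest(d2, ntree = 500, seed = 1)
  expect_true(all(oob_predict(f, d2)$covered))
})

test_that("OOB predictions carry no response leakage on pure noise", {
  set.seed(21)
  n <- 250
  d <- sf_dataset(matrix(runif(n * 10), n), rnorm(n), "regression")
  f <- grow_forest(d, ntree = 100, nodesize = 5, seed = 22)
  oob <- oob_predict(f, d, impute_uncovered = TRUE)
  smse_oob <- standardized_mse(d$y, oob$values)
  smse_inbag <- standardized_mse(d$y, predict(f, d$X))
  expect_gt(smse_oob, 85)
  expect_lt(smse_oob, 120)
  expect_lt(smse_inbag, 70)  # the forbidden in-bag path overfits visibly
})
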