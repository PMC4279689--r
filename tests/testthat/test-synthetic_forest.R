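small_cfg <- function(seed = 1, grid = c(1, 3, 5, 15), ntree = 60)
  synthetic_config(nodesize_grid = grid, ntree = ntree, seed = seed)

test_that("synthetic feature counts are D (regression) and D(J-1) (multiclass)", {
  d <- make_toy_regression(n = 70)
  syn <- build_synthetic_features(d, small_cfg())
  expect_identical(syn$q, 4L)
  expect_identical(length(syn$machine_map), 4L)
  expect_false(anyNA(syn$columns))

  dm <- make_toy_multiclass(n = 90, J = 3)
  synm <- build_synthetic_features(dm, small_cfg())
  expect_identical(synm$q, 4L * 2L)  # D * (J - 1)
  expect_identical(unname(lengths(synm$machine_map)), rep(2L, 4L))

  expect_error(synthetic_config(nodesize_grid = c(1, 5, 5)), "distinct")
})

test_that("the grid is pruned to values below n and cannot be empty", {
  d <- make_toy_regression(n = 40)
  syn <- build_synthetic_features(d, small_cfg(grid = c(1, 5, 40, 100)))
  expect_identical(syn$grid, c(1L, 5L))
  expect_error(build_synthetic_features(d, small_cfg(grid = c(50, 100))),
               "empty")
})

test_that("synthetic columns are the machines' OOB predictions", {
  d <- make_toy_regression(n = 60)
  cfg <- small_cfg(seed = 8)
  syn <- build_synthetic_features(d, cfg)
  # rebuild machine 2 independently: same seed convention, same OOB values
  f2 <- grow_forest(d, ntree = cfg$ntree, mtry = compute_mtry(d$p),
                    nodesize = cfg$nodesize_grid[2], seed = cfg$seed + 2L)
  oob <- oob_predict(f2, d, impute_uncovered = TRUE)
  expect_equal(unname(syn$columns[, 2]), unname(oob$values), tolerance = 1e-12)
})

test_that("fit_srf wires the hyperforest to the augmented matrix", {
  d <- make_toy_regression(n = 70)
  srf <- fit_srf(d, small_cfg(seed = 5))
  expect_identical(srf$hyperforest$training_p, d$p + srf$synthetic$q)
  expect_identical(srf$hyperforest$params$nodesize, 5L)
  expect_identical(srf$hyperforest$params$mtry,
                   compute_mtry(d$p + srf$synthetic$q))
  # hyper mtry on the original dimension when asked
  cfg2 <- small_cfg(seed = 5); cfg2$hyper_mtry_on <- "original"
  srf2 <- fit_srf(d, cfg2)
  expect_identical(srf2$hyperforest$params$mtry, compute_mtry(d$p))
})

test_that("predict_srf is batch-invariant and consistent with the OOB path", {
  d <- gen_friedman1(200, seed = 3)
  srf <- fit_srf(d, small_cfg(seed = 2, grid = c(1, 3, 5, 15, 50), ntree = 200))
  set.seed(4)
  Xnew <- matrix(runif(30 * d$p), 30)
  whole <- predict(srf, Xnew)
  one_by_one <- vapply(seq_len(30), function(i)
    predict(srf, Xnew[i, , drop = FALSE]), numeric(1))
  expect_equal(whole, one_by_one, tolerance = 1e-12)

  # test-path predictions on the training X track the hyperforest's OOB
  # values; correlation sits near 0.93 (the test path feeds the hyperforest
  # sharper in-bag synthetic columns than the OOB columns it trained on)
  oob <- oob_predict(srf$hyperforest,
                     sf_dataset(cbind(d$X, srf$synthetic$columns), d$y,
                                "regression"),
                     impute_uncovered = TRUE)
  expect_gt(stats::cor(predict(srf, d$X), oob$values), 0.9)
})

test_that("multiclass SRF predictions are row-stochastic", {
  dm <- make_toy_multiclass(n = 90, J = 3)
  srf <- fit_srf(dm, small_cfg(seed = 6))
  pr <- predict(srf, dm$X[1:20, ])
  expect_equal(rowSums(pr), rep(1, 20), tolerance = 1e-12)
})

test_that("select_rfopt equals a brute-force OOB-error scan", {
  d <- make_toy_regression(n = 70, seed = 10)
  syn <- build_synthetic_features(d, small_cfg(seed = 10))
  opt <- select_rfopt(syn$forests, d)
  errs <- vapply(syn$forests, oob_error, numeric(1), data = d)
  expect_equal(opt$errors, errs)
  expect_identical(opt$index, which.min(errs))
  expect_identical(opt$nodesize, syn$grid[which.min(errs)])
  # single-machine portfolio returns that machine
  opt1 <- select_rfopt(syn$forests[2], d)
  expect_identical(opt1$nodesize, syn$grid[2])

  dm <- make_toy_multiclass(n = 90)
  synm <- build_synthetic_features(dm, small_cfg(seed = 11))
  optm <- select_rfopt(synm$forests, dm)
  errsm <- vapply(synm$forests, oob_error, numeric(1), data = dm)
  expect_identical(optm$index, which.min(errsm))
})
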