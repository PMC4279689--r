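test_that("cobra_predict matches hand-enumerated closeness sets", {
  col <- cobra_collective(matrix(c(1, 2, 10)), c(1, 2, 10))
  expect_equal(cobra_predict(col, 1.5, eps = 0.6), 1.5)      # mean(1, 2)
  expect_equal(cobra_predict(col, 1.0, eps = 0), 1)          # exact match only
  expect_equal(cobra_predict(col, 9.5, eps = 0.6), 10)
  expect_equal(cobra_predict(col, 100, eps = Inf), mean(c(1, 2, 10)))
  expect_warning(p <- cobra_predict(col, 100, eps = 0.1), "empty neighbour")
  expect_equal(p, mean(c(1, 2, 10)))                         # fallback

  # multi-machine random case against the R enumeration oracle
  set.seed(31)
  tp <- matrix(rnorm(40 * 5), 40)
  ty <- rnorm(40)
  colm <- cobra_collective(tp, ty)
  for (eps in c(0.2, 0.7, 1.5)) {
    for (alpha in c(1, 0.5)) {
      test_pred <- rnorm(5)
      expect_equal(
        suppressWarnings(cobra_predict(colm, test_pred, eps, alpha_frac = alpha)),
        r_cobra_one(tp, ty, test_pred, eps, alpha))
    }
  }
})

test_that("cobra predictions are means over subsets of train_y", {
  set.seed(32)
  tp <- matrix(rnorm(50 * 3), 50)
  ty <- rnorm(50)
  col <- cobra_collective(tp, ty)
  test <- matrix(rnorm(20 * 3), 20)
  res <- suppressWarnings(cobra_predict(col, test, eps = 0.8, details = TRUE))
  expect_true(all(res$pred >= min(ty) & res$pred <= max(ty)))
  # enlarging eps never shrinks the neighbour set
  res2 <- suppressWarnings(cobra_predict(col, test, eps = 1.6, details = TRUE))
  expect_true(all(res2$n_neighbors >= res$n_neighbors))
})

test_that("calibrate_eps equals a brute-force scan over the same grid", {
  set.seed(33)
  tp <- matrix(rnorm(60 * 4), 60)
  ty <- tp[, 1] + rnorm(60, sd = 0.1)
  col <- cobra_collective(tp, ty)
  hp <- matrix(rnorm(25 * 4), 25)
  hy <- hp[, 1] + rnorm(25, sd = 0.1)
  cal <- calibrate_eps(col, hp, hy, grid_size = 40)
  brute <- vapply(cal$grid, function(e) {
    pred <- suppressWarnings(cobra_predict(col, hp, e))
    mean((pred - hy)^2)
  }, numeric(1))
  expect_equal(cal$risk, brute, tolerance = 1e-12)
  expect_equal(cal$eps, cal$grid[which.min(brute)])
})

test_that("calibration beats the grid endpoints on a reproducible toy", {
  # one machine reproduces y exactly; tuned eps must beat both extremes
  set.seed(34)
  n <- 200
  x <- runif(n)
  machines <- cbind(2 * x, rnorm(n))      # machine 1 = y, machine 2 = junk
  y <- 2 * x
  col <- cobra_collective(machines, y)
  cal <- calibrate_eps(col, grid_size = 200, alpha_frac = 0.5)
  expect_lte(cal$risk[which.min(cal$risk)], cal$risk[1])
  expect_lte(cal$risk[which.min(cal$risk)], cal$risk[length(cal$risk)])
  # ties break toward the smallest eps
  expect_identical(cal$eps, cal$grid[which.min(cal$risk)])
})

test_that("degenerate collectives are handled", {
  col <- cobra_collective(matrix(1, 10, 2), rnorm(10))
  expect_warning(cal <- calibrate_eps(col, grid_size = 10), "equal")
  expect_gt(cal$eps, 0)
  expect_error(cobra_predict(col, c(1, 1), eps = -1), "non-negative")
  expect_error(cobra_collective(matrix(NA_real_, 3, 1), 1:3), "missing")
})
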