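#' Default mtry rule
#'
#' Number of candidate features tried at each node split, computed from the
#' feature count as the first integer strictly greater than `p/3` (so
#' `p = 10` gives 4, `p = 3` gives 2), clamped to `[1, p]`. The alternative
#' `"ceiling"` rule uses `ceiling(p/3)`; the two differ only when `p` is a
#' multiple of 3.
#'
#' @param p number of features (positive integer).
#' @param rule `"strict"` (default, first integer greater than `p/3`) or
#'   `"ceiling"`.
#' @return Integer mtry value in `[1, p]`.
#' @examples
#' compute_mtry(10)  # 4
#' compute_mtry(3)   # 2
#' compute_mtry(3, rule = "ceiling")  # 1
#' @export
compute_mtry <- function(p, rule = c("strict", "ceiling")) {
  rule <- match.arg(rule)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1)
    stop("p must be a positive integer")
  p <- as.integer(p)
  m <- if (rule == "strict") as.integer(p %/% 3L) + 1L else as.integer(ceiling(p / 3))
  max(1L, min(p, m))
}

#' Grow a random forest
#'
#' Bagged CART trees: each tree is grown on an independent bootstrap sample of
#' size n (with replacement); at every node a random subset of `mtry` features
#' is considered and the best split (variance reduction for regression, Gini
#' for multiclass) is taken; trees grow as deep as possible, splitting any
#' node that holds at least `2 * nodesize` bootstrap cases (the reference
#' forest's semantics). Predictions are convex combinations of training outcomes
#' (regression) or averaged terminal-node class frequencies (multiclass).
#'
#' Runs are exactly reproducible: all randomness flows from `seed`.
#'
#' @param data an [sf_dataset()].
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split; default [compute_mtry()] of `p`.
#' @param nodesize the forest's smoothing bandwidth: a node is split only
#'   while it holds at least `2 * nodesize` bootstrap cases, so terminal
#'   nodes hold at most `2 * nodesize - 1` (and possibly very few) cases.
#'   `nodesize = n` forces single-root trees.
#' @param seed integer seed.
#' @return An `sf_forest` with the tree ensemble, the `ntree x n` in-bag
#'   multiplicity matrix (`inbag`), and the fit parameters.
#' @seealso [oob_predict()], [predict.sf_forest()]
#' @export
grow_forest <- function(data, ntree = 500L, mtry = NULL, nodesize = 5L, seed = 1L) {
  stopifnot(inherits(data, "sf_dataset"))
  if (is.null(mtry)) mtry <- compute_mtry(data$p)
  ntree <- as.integer(ntree); mtry <- as.integer(mtry); nodesize <- as.integer(nodesize)
  if (ntree < 1L) stop("ntree must be >= 1")
  if (mtry < 1L || mtry > data$p) stop("mtry must lie in [1, p]")
  if (nodesize < 1L) stop("nodesize must be >= 1")
  if (nodesize > data$n) stop("nodesize exceeds the sample size")

  J <- if (is_multiclass(data)) data$J else 0L
  yreg <- if (J == 0L) data$y else numeric(data$n)
  ycls <- if (J > 0L) data$y else integer(data$n)
  set.seed(seed)
  fit <- cpp_grow_forest(data$X, yreg, ycls, J, ntree, mtry, nodesize)
  structure(list(
    trees = fit$trees, inbag = fit$inbag, task = data$task, J = J,
    params = list(ntree = ntree, mtry = mtry, nodesize = nodesize, seed = seed),
    training_n = data$n, training_p = data$p,
    y_range = if (J == 0L) range(data$y) else NULL
  ), class = "sf_forest")
}

#' @export
print.sf_forest <- function(x, ...) {
  cat(sprintf("<sf_forest> %s: ntree = %d, mtry = %d, nodesize = %d (n = %d, p = %d)\n",
              x$task, x$params$ntree, x$params$mtry, x$params$nodesize,
              x$training_n, x$training_p))
  invisible(x)
}

#' Predict from a random forest
#'
#' @param object an `sf_forest`.
#' @param newdata numeric matrix with `training_p` columns.
#' @param bytree if `TRUE` (regression only) return the `n x ntree` matrix of
#'   per-tree predictions instead of the ensemble average.
#' @param ... unused.
#' @return Regression: numeric vector (or per-tree matrix). Multiclass:
#'   row-stochastic `n x J` probability matrix.
#' @export
predict.sf_forest <- function(object, newdata, bytree = FALSE, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$training_p)
    stop(sprintf("newdata has %d columns but the forest was trained on %d",
                 ncol(newdata), object$training_p))
  out <- cpp_predict_forest(object$trees, newdata, object$J, isTRUE(bytree))
  if (object$J == 0L && !isTRUE(bytree)) drop(out) else out
}

#' Out-of-bag predictions
#'
#' Aggregates, for each training case, only the trees whose bootstrap sample
#' excluded that case, yielding a cross-validated prediction that never uses
#' the case's own response. Cases in every bootstrap (possible at small
#' `ntree`) are flagged uncovered and returned as `NA`, never silently zero.
#'
#' @param forest an `sf_forest`.
#' @param data the [sf_dataset()] the forest was fitted on.
#' @param impute_uncovered if `TRUE`, uncovered cases are filled with the
#'   full-forest prediction (keeps downstream feature matrices complete while
#'   leaving covered cases strictly out-of-sample).
#' @return List of class `sf_oob`: `values` (n-vector or n x J matrix,
#'   `NA` where uncovered unless imputed), `covered` (logical n-vector),
#'   `n_trees_oob` (trees aggregated per case).
#' @export
oob_predict <- function(forest, data, impute_uncovered = FALSE) {
  stopifnot(inherits(forest, "sf_forest"), inherits(data, "sf_dataset"))
  if (data$n != forest$training_n)
    stop("data does not match the forest's training sample size")
  res <- cpp_oob_predict(forest$trees, forest$inbag, data$X, forest$J)
  values <- if (forest$J == 0L) drop(res$values) else res$values
  covered <- res$covered
  if (impute_uncovered && any(!covered)) {
    full <- predict(forest, data$X)
    if (forest$J == 0L) values[!covered] <- full[!covered]
    else values[!covered, ] <- full[!covered, , drop = FALSE]
  }
  structure(list(values = values, covered = covered,
                 n_trees_oob = res$n_trees_oob), class = "sf_oob")
}

#' Out-of-bag prediction error
#'
#' Mean squared error (regression) or normalized Brier score (multiclass) of
#' the out-of-bag predictions; the metric the nodesize-optimized baseline
#' minimizes. Uncovered cases are dropped.
#'
#' @param forest an `sf_forest`.
#' @param data the training [sf_dataset()].
#' @param metric multiclass only: `"brier"` (default) or `"misclass"`.
#' @return A single number.
#' @export
oob_error <- function(forest, data, metric = c("brier", "misclass")) {
  metric <- match.arg(metric)
  oob <- oob_predict(forest, data)
  keep <- oob$covered
  if (forest$J == 0L) {
    mean((data$y[keep] - oob$values[keep])^2)
  } else if (metric == "brier") {
    brier_score(oob$values[keep, , drop = FALSE], data$y[keep])
  } else {
    mean(max.col(oob$values[keep, , drop = FALSE]) - 1L != data$y[keep])
  }
}
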