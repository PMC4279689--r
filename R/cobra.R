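#' COBRA regression collective
#'
#' COBRA (COmBined Regression Alternative) aggregates a portfolio of
#' regression machines with zero-one proximity weights: a training case gets
#' weight 1 for a test point when, for enough machines, the machine's
#' prediction at the training case lies within `eps` of its prediction at the
#' test point; the COBRA prediction is the plain mean of the training outcomes
#' over the weight-1 set. It is a locally weighted averaging estimator whose
#' weights are exactly \{0, 1\} — the contrast with a forest's arbitrary
#' convex weights.
#'
#' `cobra_collective()` just bundles the machine predictions at the training
#' points (out-of-bag predictions when the machines were fitted on the same
#' data) with the training outcomes.
#'
#' @param train_preds n x M matrix: machine m's prediction at training case i.
#' @param train_y training outcomes (length n).
#' @return An object of class `sf_cobra`.
#' @export
cobra_collective <- function(train_preds, train_y) {
  train_preds <- as.matrix(train_preds)
  storage.mode(train_preds) <- "double"
  if (nrow(train_preds) != length(train_y)) stop("train_preds and train_y disagree on n")
  if (anyNA(train_preds) || anyNA(train_y)) stop("missing machine predictions or outcomes")
  if (ncol(train_preds) < 1L) stop("need at least one machine")
  structure(list(train_preds = train_preds, train_y = as.numeric(train_y),
                 M = ncol(train_preds)), class = "sf_cobra")
}

cobra_kmin <- function(M, alpha_frac) {
  if (alpha_frac <= 0 || alpha_frac > 1) stop("alpha_frac must lie in (0, 1]")
  max(1L, as.integer(ceiling(alpha_frac * M)))
}

#' COBRA prediction
#'
#' @param collective an [cobra_collective()].
#' @param test_preds M-vector of machine predictions at one test point, or an
#'   n_test x M matrix for a batch.
#' @param eps closeness threshold (non-negative; `Inf` makes every training
#'   case a neighbour, giving `mean(train_y)`).
#' @param alpha_frac fraction of machines that must agree (default 1 =
#'   unanimity, the reference method's rule; 0.5 gives majority agreement).
#' @param details if `TRUE` return a list with the per-test neighbour counts
#'   and fallback count as well.
#' @return Numeric vector of predictions (means over subsets of `train_y`,
#'   hence always within `[min(train_y), max(train_y)]`). An empty neighbour
#'   set falls back to `mean(train_y)` with a warning.
#' @examples
#' col <- cobra_collective(matrix(c(1, 2, 10)), c(1, 2, 10))
#' cobra_predict(col, 1.5, eps = 0.6)  # mean(1, 2) = 1.5
#' @export
cobra_predict <- function(collective, test_preds, eps, alpha_frac = 1,
                          details = FALSE) {
  stopifnot(inherits(collective, "sf_cobra"))
  if (eps < 0) stop("eps must be non-negative")
  if (is.null(dim(test_preds))) test_preds <- matrix(test_preds, ncol = collective$M)
  test_preds <- as.matrix(test_preds)
  if (ncol(test_preds) != collective$M)
    stop("test_preds must have one column per machine")
  storage.mode(test_preds) <- "double"
  kmin <- cobra_kmin(collective$M, alpha_frac)
  res <- cpp_cobra_predict(collective$train_preds, collective$train_y,
                           test_preds, eps, kmin, integer(0))
  if (res$n_fallback > 0)
    warning(sprintf("%d test case(s) had an empty neighbour set; fell back to mean(train_y)",
                    res$n_fallback))
  if (details) res else res$pred
}

#' Calibrate the COBRA closeness threshold
#'
#' Scans a linear grid of `grid_size` epsilon values over
#' `(0, max machine prediction spread]` and returns the value minimizing the
#' squared-error risk of [cobra_predict()] on a holdout set; ties break toward
#' the smallest epsilon. When no holdout is given, the training points
#' themselves are used with each case excluded from its own neighbour set
#' (leave-one-out style), which is the right mode when the machine columns are
#' out-of-bag predictions.
#'
#' @param collective an [cobra_collective()].
#' @param holdout_preds,holdout_y optional holdout machine predictions
#'   (n_h x M) and outcomes.
#' @param grid_size number of epsilon values (default 200).
#' @param alpha_frac as in [cobra_predict()].
#' @return List: `eps` (chosen value), `grid`, `risk` (per grid point).
#' @export
calibrate_eps <- function(collective, holdout_preds = NULL, holdout_y = NULL,
                          grid_size = 200L, alpha_frac = 1) {
  stopifnot(inherits(collective, "sf_cobra"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("grid_size must be >= 2")
  spread <- max(apply(collective$train_preds, 2, function(v) diff(range(v))))
  if (spread <= 0) {
    warning("all machine predictions are equal; returning the smallest grid value")
    spread <- 1
  }
  grid <- seq(spread / grid_size, spread, length.out = grid_size)
  if (is.null(holdout_preds)) {
    holdout_preds <- collective$train_preds
    holdout_y <- collective$train_y
    self_idx <- seq_len(nrow(holdout_preds)) - 1L
  } else {
    holdout_preds <- as.matrix(holdout_preds)
    storage.mode(holdout_preds) <- "double"
    if (nrow(holdout_preds) == 0L) stop("holdout is empty")
    self_idx <- integer(0)
  }
  kmin <- cobra_kmin(collective$M, alpha_frac)
  risk <- cpp_cobra_risk(collective$train_preds, collective$train_y,
                         holdout_preds, as.numeric(holdout_y), grid, kmin,
                         self_idx)
  best <- which.min(risk)  # first minimum = smallest eps
  list(eps = grid[best], grid = grid, risk = risk)
}
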