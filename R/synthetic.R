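#' Configuration for a synthetic random forest
#'
#' A synthetic random forest (SRF) grows one component forest per value of a
#' nodesize grid, turns each component's out-of-bag predictions into synthetic
#' features, and fits a secondary "hyperforest" on the original features
#' augmented with the synthetic ones. The grid should span a handful of small
#' values, a few intermediate values, and a few large values; values `>= n`
#' are pruned at fit time.
#'
#' `ntree` and `mtry` are held fixed across all component forests (varying
#' mtry alongside nodesize is deliberately unsupported: joint grids can hurt
#' performance and inflate the synthetic dimension).
#'
#' @param nodesize_grid ascending vector of distinct positive integers.
#' @param ntree trees per forest (default 500).
#' @param hyper_nodesize nodesize of the hyperforest (default 5).
#' @param mtry_rule `"strict"` or `"ceiling"`, see [compute_mtry()].
#' @param hyper_mtry_on compute the hyperforest's mtry from the `"augmented"`
#'   dimension p + q (default) or from the `"original"` p.
#' @param seed base seed; component forest j uses `seed + j`, the hyperforest
#'   `seed - 1`.
#' @return An object of class `sf_config`.
#' @export
synthetic_config <- function(nodesize_grid = c(1:10, 20, 30, 50, 100),
                             ntree = 500L, hyper_nodesize = 5L,
                             mtry_rule = c("strict", "ceiling"),
                             hyper_mtry_on = c("augmented", "original"),
                             seed = 1L) {
  mtry_rule <- match.arg(mtry_rule)
  hyper_mtry_on <- match.arg(hyper_mtry_on)
  nodesize_grid <- as.integer(nodesize_grid)
  if (any(nodesize_grid < 1L)) stop("nodesize grid values must be >= 1")
  if (anyDuplicated(nodesize_grid)) stop("nodesize grid values must be distinct")
  if (is.unsorted(nodesize_grid)) stop("nodesize grid must be ascending")
  structure(list(nodesize_grid = nodesize_grid, ntree = as.integer(ntree),
                 hyper_nodesize = as.integer(hyper_nodesize),
                 mtry_rule = mtry_rule, hyper_mtry_on = hyper_mtry_on,
                 seed = as.integer(seed)),
            class = "sf_config")
}

prune_grid <- function(grid, n) {
  grid <- grid[grid < n]
  if (length(grid) == 0L) stop("nodesize grid is empty after pruning to values < n")
  grid
}

#' Build synthetic features from a nodesize grid of forests
#'
#' Fits one forest per grid value (shared `ntree` and mtry) and assembles each
#' forest's out-of-bag predictions into synthetic feature columns: one column
#' per machine for regression, the first `J - 1` class probabilities per
#' machine for multiclass (the last is dropped as linearly dependent). Every
#' column is an out-of-bag quantity, built without the case's own response;
#' the rare case present in all of a machine's bootstraps is imputed with that
#' machine's full-forest prediction.
#'
#' @param data an [sf_dataset()].
#' @param config an [synthetic_config()].
#' @return List of class `sf_synthetic`: `columns` (n x q matrix),
#'   `machine_map` (nodesize value -> column indices), `q`, `grid` (pruned),
#'   `forests` (the component `sf_forest`s).
#' @export
build_synthetic_features <- function(data, config = synthetic_config()) {
  stopifnot(inherits(data, "sf_dataset"), inherits(config, "sf_config"))
  grid <- prune_grid(config$nodesize_grid, data$n)
  mtry <- compute_mtry(data$p, config$mtry_rule)
  J <- if (is_multiclass(data)) data$J else 0L
  ncol_each <- if (J > 0L) J - 1L else 1L

  forests <- vector("list", length(grid))
  cols <- matrix(NA_real_, data$n, length(grid) * ncol_each)
  machine_map <- vector("list", length(grid))
  names(machine_map) <- as.character(grid)
  for (j in seq_along(grid)) {
    forests[[j]] <- grow_forest(data, ntree = config$ntree, mtry = mtry,
                                nodesize = grid[j], seed = config$seed + j)
    oob <- oob_predict(forests[[j]], data, impute_uncovered = TRUE)
    idx <- (j - 1L) * ncol_each + seq_len(ncol_each)
    cols[, idx] <- if (J > 0L) oob$values[, seq_len(ncol_each), drop = FALSE]
                   else oob$values
    machine_map[[j]] <- idx
  }
  colnames(cols) <- unlist(lapply(grid, function(g)
    if (J > 0L) paste0("syn.ns", g, ".c", seq_len(ncol_each) - 1L)
    else paste0("syn.ns", g)))
  structure(list(columns = cols, machine_map = machine_map,
                 q = ncol(cols), grid = grid, forests = forests),
            class = "sf_synthetic")
}

#' Fit a synthetic random forest
#'
#' Runs the full pipeline: component forests over the nodesize grid, synthetic
#' features from their out-of-bag predictions, then the hyperforest on
#' `[X | synthetic columns]` with `nodesize = hyper_nodesize`. The augmented
#' column order is the original p features followed by the synthetic columns in
#' grid order. Also records the nodesize-optimized baseline (`rfopt`): the
#' grid value whose component forest has the smallest out-of-bag error.
#'
#' @param data an [sf_dataset()].
#' @param config an [synthetic_config()].
#' @return An `sf_srf` model with elements `hyperforest`, `synthetic`
#'   (component forests and training columns), `config`, `rfopt_nodesize`,
#'   `rfopt_index`, `oob_errors`, `task`.
#' @seealso [predict.sf_srf()], [select_rfopt()]
#' @export
fit_srf <- function(data, config = synthetic_config()) {
  syn <- build_synthetic_features(data, config)
  aug <- cbind(data$X, syn$columns)
  aug_data <- sf_dataset(aug, data$y, data$task)
  hyper_mtry <- switch(config$hyper_mtry_on,
    augmented = compute_mtry(ncol(aug), config$mtry_rule),
    original  = compute_mtry(data$p, config$mtry_rule))
  hyper <- grow_forest(aug_data, ntree = config$ntree, mtry = hyper_mtry,
                       nodesize = config$hyper_nodesize, seed = config$seed - 1L)
  opt <- select_rfopt(syn$forests, data)
  structure(list(hyperforest = hyper, synthetic = syn, config = config,
                 rfopt_nodesize = opt$nodesize, rfopt_index = opt$index,
                 oob_errors = opt$errors, task = data$task,
                 training_p = data$p),
            class = "sf_srf")
}

#' @export
print.sf_srf <- function(x, ...) {
  cat(sprintf(paste0("<sf_srf> %s: %d machines (nodesize grid %s), q = %d ",
                     "synthetic features, rfopt nodesize = %d\n"),
              x$task, length(x$synthetic$grid),
              paste(x$synthetic$grid, collapse = ","),
              x$synthetic$q, x$rfopt_nodesize))
  invisible(x)
}

#' Predict from a synthetic random forest
#'
#' New cases are out-of-sample for every component forest, so their synthetic
#' features are full-forest predictions from the stored components (no
#' out-of-bag discipline needed); the hyperforest then predicts on the
#' augmented rows.
#'
#' @param object an `sf_srf`.
#' @param newdata numeric matrix with the original p columns.
#' @param ... unused.
#' @return As [predict.sf_forest()].
#' @export
predict.sf_srf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$training_p)
    stop(sprintf("newdata has %d columns but the model was trained on %d",
                 ncol(newdata), object$training_p))
  aug <- cbind(newdata, synthetic_features_for(object, newdata))
  predict(object$hyperforest, aug)
}

# Full-forest synthetic columns for new cases, in machine_map order.
synthetic_features_for <- function(object, newdata) {
  syn <- object$synthetic
  J <- if (object$task == "multiclass") ncol(syn$columns) / length(syn$grid) + 1L else 0L
  cols <- matrix(NA_real_, nrow(newdata), syn$q)
  for (j in seq_along(syn$grid)) {
    pred <- predict(syn$forests[[j]], newdata)
    idx <- syn$machine_map[[j]]
    cols[, idx] <- if (J > 0L) pred[, seq_along(idx), drop = FALSE] else pred
  }
  colnames(cols) <- colnames(syn$columns)
  cols
}

#' Select the nodesize-optimized forest
#'
#' Scans the component forests and returns the one with the smallest
#' out-of-bag error (mean squared error for regression, normalized Brier for
#' multiclass by default); ties break toward the smaller nodesize. This is the
#' globally tuned single-forest baseline the synthetic forest is compared
#' against.
#'
#' @param forests list of component `sf_forest`s (ascending nodesize order).
#' @param data the training [sf_dataset()].
#' @param metric see [oob_error()].
#' @return List: `nodesize`, `index`, `forest`, `errors` (per machine).
#' @export
select_rfopt <- function(forests, data, metric = c("brier", "misclass")) {
  metric <- match.arg(metric)
  stopifnot(length(forests) >= 1L)
  errors <- vapply(forests, oob_error, numeric(1), data = data, metric = metric)
  best <- which.min(errors)  # first minimum = smallest nodesize (ascending grid)
  list(nodesize = forests[[best]]$params$nodesize, index = best,
       forest = forests[[best]], errors = errors)
}
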