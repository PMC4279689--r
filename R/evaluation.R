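#' k-fold cross-validated performance
#'
#' Splits the data into k near-equal seeded folds (stratified by class for
#' multiclass tasks), fits the method on each training complement, pools the
#' out-of-fold predictions, and scores them: standardized MSE for regression
#' (standardized by the full-response variance, so a constant-mean predictor
#' anchors near 100) or normalized Brier for multiclass.
#'
#' @param data an [sf_dataset()].
#' @param method a fitting function `function(train_data, test_X)` returning
#'   predictions, or a method name understood by [make_method()].
#' @param k number of folds (default 10; must not exceed n).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [make_method()] when `method` is a name.
#' @return List: `metric`, `predictions` (pooled, in data order), `folds`
#'   (fold id per case).
#' @export
kfold_cv <- function(data, method, k = 10L, seed = 1L, ...) {
  stopifnot(inherits(data, "sf_dataset"))
  k <- as.integer(k)
  if (k < 2L || k > data$n) stop("k must lie in [2, n]")
  if (is.character(method)) method <- make_method(method, ...)
  set.seed(seed)
  if (is_multiclass(data)) {
    folds <- integer(data$n)
    for (j in 0:(data$J - 1L)) {
      idx <- which(data$y == j)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), data$n))
  }
  pred <- if (is_multiclass(data)) matrix(NA_real_, data$n, data$J) else
    rep(NA_real_, data$n)
  for (f in seq_len(k)) {
    hold <- folds == f
    train <- sf_dataset(data$X[!hold, , drop = FALSE], data$y[!hold], data$task)
    p <- method(train, data$X[hold, , drop = FALSE])
    if (is_multiclass(data)) pred[hold, ] <- p else pred[hold] <- p
  }
  metric <- score_predictions(data, pred,
                              var_y = if (!is_multiclass(data))
                                mean((data$y - mean(data$y))^2) else NULL)
  list(metric = metric, predictions = pred, folds = folds)
}

#' Benchmark method constructors
#'
#' Returns a `function(train_data, test_X)` for one of the four benchmark
#' methods: `"RF"` (a single forest at `nodesize = rf_nodesize`), `"RFopt"`
#' (the nodesize-grid forest with the smallest out-of-bag error), `"SRF"`
#' (the synthetic random forest), or `"COBRA"` (regression only; the
#' zero-one-weight collective over the same nodesize-grid machines, with the
#' closeness threshold calibrated on a `grid_size`-point grid).
#'
#' @param method method name.
#' @param config an [synthetic_config()]; its `seed` drives the fit.
#' @param rf_nodesize nodesize of the plain-RF baseline (default 5, matching
#'   the hyperforest so the two differ only by the synthetic features).
#' @param alpha_frac,grid_size COBRA settings, see [cobra_predict()] and
#'   [calibrate_eps()].
#' @return A fitting function.
#' @export
make_method <- function(method = c("RF", "RFopt", "SRF", "COBRA"),
                        config = synthetic_config(), rf_nodesize = 5L,
                        alpha_frac = 1, grid_size = 200L) {
  method <- match.arg(method)
  switch(method,
    RF = function(train, test_X) {
      f <- grow_forest(train, ntree = config$ntree,
                       mtry = compute_mtry(train$p, config$mtry_rule),
                       nodesize = rf_nodesize, seed = config$seed - 2L)
      predict(f, test_X)
    },
    RFopt = function(train, test_X) {
      syn <- build_synthetic_features(train, config)
      opt <- select_rfopt(syn$forests, train)
      predict(opt$forest, test_X)
    },
    SRF = function(train, test_X) {
      predict(fit_srf(train, config), test_X)
    },
    COBRA = function(train, test_X) {
      if (is_multiclass(train)) stop("COBRA supports regression only")
      srf <- fit_srf(train, config)
      cobra_predict_from_srf(srf, train, test_X,
                             alpha_frac = alpha_frac, grid_size = grid_size)
    })
}

# COBRA using an SRF's machines: OOB columns at training points, full-forest
# columns at test points, eps calibrated on the training points (self-excluded).
cobra_predict_from_srf <- function(srf, train, test_X, alpha_frac = 1,
                                   grid_size = 200L) {
  collective <- cobra_collective(srf$synthetic$columns, train$y)
  cal <- calibrate_eps(collective, grid_size = grid_size,
                       alpha_frac = alpha_frac)
  test_preds <- synthetic_features_for(srf, as.matrix(test_X))
  suppressWarnings(cobra_predict(collective, test_preds, eps = cal$eps,
                                 alpha_frac = alpha_frac))
}

#' Replicated train/test benchmark
#'
#' The simulation protocol behind the benchmark tables: per replication, draw
#' a fresh training set of size `n` and an independent test set of size
#' `n_test` from the named generator, fit every method on the identical
#' training set, and score each on the identical test set (standardized MSE
#' for regression, normalized Brier x 100 for multiclass). Per-replication
#' seeds are derived from `base_seed`, so a run is fully reproducible and
#' every method sees the same draws.
#'
#' The synthetic-forest family shares one fit per replication: RFopt is the
#' best component of the SRF's nodesize grid and COBRA reuses the same
#' machines, as in the benchmark design.
#'
#' @param name generator name, see [gen_benchmark()].
#' @param methods subset of `c("RF", "RFopt", "SRF", "COBRA")`.
#' @param reps number of replications.
#' @param n,n_test training and test sample sizes (defaults 250 and 5000).
#' @param config an [synthetic_config()] (its seed field is overridden per
#'   replication).
#' @param base_seed master seed.
#' @param extra_noise_features inert columns appended to train and test.
#' @param rf_nodesize,alpha_frac,grid_size as in [make_method()].
#' @return A `data.frame` with columns `dataset`, `rep`, `method`, `metric`,
#'   `seed_train`, `seed_test` (class `sf_benchmark`).
#' @export
replicate_benchmark <- function(name, methods = c("RF", "RFopt", "SRF"),
                                reps = 100L, n = 250L, n_test = 5000L,
                                config = synthetic_config(), base_seed = 1L,
                                extra_noise_features = 0L, rf_nodesize = 5L,
                                alpha_frac = 1, grid_size = 200L) {
  stopifnot(reps >= 1L)
  methods <- match.arg(methods, c("RF", "RFopt", "SRF", "COBRA"), several.ok = TRUE)
  set.seed(base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 10L, 2L * reps), ncol = 2L)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    s_tr <- seeds[r, 1]; s_te <- seeds[r, 2]
    train <- gen_benchmark(name, n, seed = s_tr,
                           extra_noise_features = extra_noise_features)
    test <- gen_benchmark(name, n_test, seed = s_te,
                          extra_noise_features = extra_noise_features)
    if (is_multiclass(train) && "COBRA" %in% methods)
      stop("COBRA supports regression only")
    cfg <- config
    cfg$seed <- s_tr
    need_srf <- any(c("SRF", "RFopt", "COBRA") %in% methods)
    srf <- if (need_srf) fit_srf(train, cfg) else NULL
    vals <- vapply(methods, function(m) {
      pred <- switch(m,
        SRF = predict(srf, test$X),
        RFopt = predict(srf$synthetic$forests[[srf$rfopt_index]], test$X),
        RF = {
          f <- grow_forest(train, ntree = cfg$ntree,
                           mtry = compute_mtry(train$p, cfg$mtry_rule),
                           nodesize = rf_nodesize, seed = cfg$seed - 2L)
          predict(f, test$X)
        },
        COBRA = cobra_predict_from_srf(srf, train, test$X,
                                       alpha_frac = alpha_frac,
                                       grid_size = grid_size))
      score_predictions(test, pred)
    }, numeric(1))
    out[[r]] <- data.frame(dataset = name, rep = r, method = methods,
                           metric = unname(vals), seed_train = s_tr,
                           seed_test = s_te, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("sf_benchmark", "data.frame")
  res
}

#' Summarize a benchmark run
#'
#' @param result the data frame from [replicate_benchmark()] (or several
#'   row-bound together).
#' @return A `data.frame` of per-(dataset, method) mean metric, standard
#'   error over replications, and replication count, with methods in
#'   portfolio order.
#' @export
summarize_benchmark <- function(result) {
  agg <- do.call(rbind, lapply(split(result, result[c("dataset", "method")],
                                     drop = TRUE), function(d) {
    data.frame(dataset = d$dataset[1], method = d$method[1],
               mean = mean(d$metric),
               se = stats::sd(d$metric) / sqrt(nrow(d)),
               reps = nrow(d), row.names = NULL)
  }))
  ord <- c("COBRA", "RF", "RFopt", "SRF")
  agg <- agg[order(agg$dataset, match(agg$method, ord)), ]
  rownames(agg) <- NULL
  agg
}
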