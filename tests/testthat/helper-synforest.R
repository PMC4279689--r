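# Shared fixtures and independent oracles. Everything here is generated in
# code; no stored data.

make_toy_regression <- function(n = 80, p = 4, seed = 42, noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- 3 * X[, 1] - 2 * X[, 2] + rnorm(n, sd = noise_sd)
  sf_dataset(X, y, "regression")
}

make_toy_multiclass <- function(n = 90, p = 3, J = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- (findInterval(X[, 1], stats::qnorm(seq_len(J - 1) / J))) %% J
  # ensure all classes present
  y[seq_len(J)] <- 0:(J - 1)
  sf_dataset(X, y, "multiclass")
}

# independent R traversal of a stored tree: returns 1-based leaf node ids
r_tree_leaves <- function(tree, X) {
  X <- rbind(X)
  vapply(seq_len(nrow(X)), function(i) {
    node <- 1L
    while (tree$var[node] >= 0L) {
      node <- if (X[i, tree$var[node] + 1L] <= tree$thr[node])
        tree$left[node] + 1L else tree$right[node] + 1L
    }
    node
  }, integer(1))
}

# brute-force exact two-sided signed-rank p over all 2^n sign patterns
wsr_enum_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# hand COBRA: zero-one weights by direct enumeration
r_cobra_one <- function(train_preds, train_y, test_pred, eps, alpha_frac = 1) {
  M <- ncol(train_preds)
  agree <- rowSums(abs(sweep(train_preds, 2, test_pred)) <= eps)
  keep <- agree >= max(1, ceiling(alpha_frac * M))
  if (!any(keep)) mean(train_y) else mean(train_y[keep])
}
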