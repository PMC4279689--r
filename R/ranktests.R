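#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences: zeros are dropped, absolute
#' differences are ranked with midranks for ties, and the statistic is the sum
#' of ranks of the positive differences. For `n <= exact_limit` the two-sided
#' p-value is exact — computed from the full null distribution over all 2^n
#' sign assignments (via a shift-algorithm convolution, which handles
#' midranks) — as `min(1, 2 * min(P(W <= w), P(W >= w)))`; beyond that a
#' normal approximation with tie-corrected variance is used.
#'
#' @param x paired differences (at least one nonzero; all-zero input returns
#'   p = 1 with a warning).
#' @param exact_limit largest n for the exact distribution (default 25).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `statistic` (W+, sum of positive-difference ranks),
#'   `statistic_min` (`min(W+, W-)`, the "small values indicate a difference"
#'   form used in rank summary tables), `p_value`, `n` (nonzero pairs),
#'   `exact`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p_value  # exact 2/8 = 0.25
#' @export
wilcoxon_signed_rank <- function(x, exact_limit = 25L,
                                 alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, statistic_min = 0, p_value = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(x))
  w_plus <- sum(r[x > 0])
  s_tot <- n * (n + 1) / 2

  if (n <= exact_limit) {
    # null distribution of 2*W+ (doubled midranks are integers)
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge, less = p_le)
    exact <- TRUE
  } else {
    mu <- s_tot / 2
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    exact <- FALSE
  }
  list(statistic = w_plus, statistic_min = min(w_plus, s_tot - w_plus),
       p_value = p, n = n, exact = exact)
}

#' Friedman rank test with the Iman-Davenport correction
#'
#' Compares k methods across b datasets on a `b x k` metric matrix (smaller =
#' better). Each dataset ranks the methods 1..k (midranks for ties); the
#' Friedman chi-square statistic on the average ranks is converted to the less
#' conservative Iman-Davenport F statistic
#' `F = (b - 1) chi2 / (b (k - 1) - chi2)` with `(k - 1, (b - 1)(k - 1))`
#' degrees of freedom.
#'
#' @param metrics numeric `b x k` matrix, rows = datasets, columns = methods.
#' @return An object of class `sf_ranksummary`: `avg_ranks` (sums to
#'   `k (k + 1) / 2`), `chisq`, `statistic` (F), `df`, `p_value`, `b`, `k`.
#' @export
friedman_iman_davenport <- function(metrics) {
  metrics <- as.matrix(metrics)
  b <- nrow(metrics); k <- ncol(metrics)
  if (b < 2L || k < 2L) stop("need at least 2 datasets and 2 methods")
  if (anyNA(metrics)) stop("metric matrix has missing cells")
  ranks <- t(apply(metrics, 1, rank))
  rbar <- colMeans(ranks)
  chisq <- 12 * b / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  denom <- b * (k - 1) - chisq
  f_stat <- if (denom <= 0) Inf else (b - 1) * chisq / denom
  p <- stats::pf(f_stat, k - 1, (b - 1) * (k - 1), lower.tail = FALSE)
  structure(list(avg_ranks = rbar, chisq = chisq, statistic = f_stat,
                 df = c(k - 1, (b - 1) * (k - 1)), p_value = p, b = b, k = k),
            class = "sf_ranksummary")
}

#' @export
print.sf_ranksummary <- function(x, ...) {
  cat("<sf_ranksummary>\naverage ranks:\n")
  print(round(x$avg_ranks, 3))
  cat(sprintf("Friedman chi-square = %.4f; Iman-Davenport F(%d, %d) = %.4f, p = %.4g\n",
              x$chisq, x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}

#' Rank summary table over a benchmark
#'
#' Builds the method-comparison table reported for benchmark studies: the
#' average rank of every method on the diagonal, exact Wilcoxon signed-rank
#' p-values above it, and the corresponding `min(W+, W-)` statistics below it,
#' plus the Iman-Davenport overall test.
#'
#' @param metrics `b x k` matrix of per-dataset method means (smaller =
#'   better), with method column names.
#' @return List: `table` (k x k, as described), `overall`
#'   (an `sf_ranksummary`).
#' @export
rank_summary <- function(metrics) {
  metrics <- as.matrix(metrics)
  k <- ncol(metrics)
  if (is.null(colnames(metrics))) colnames(metrics) <- paste0("m", seq_len(k))
  overall <- friedman_iman_davenport(metrics)
  tab <- matrix(NA_real_, k, k, dimnames = list(colnames(metrics), colnames(metrics)))
  diag(tab) <- overall$avg_ranks
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      w <- wilcoxon_signed_rank(metrics[, i] - metrics[, j])
      tab[i, j] <- w$p_value
      tab[j, i] <- w$statistic_min
    }
  }
  list(table = tab, overall = overall)
}
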