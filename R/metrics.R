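#' Standardized mean squared error
#'
#' `100 * MSE / Var(y)`, with the variance taken over the evaluation vector
#' itself (population form, denominator n). The scale is anchored: a perfect
#' predictor scores 0 and predicting the evaluation mean scores exactly 100,
#' so 100 is the uninformed baseline on any dataset.
#'
#' @param y observed responses (length >= 2, non-constant).
#' @param yhat predictions.
#' @param var_y optional variance to standardize by (e.g. the full-response
#'   variance when pooling cross-validation folds); default `Var(y)` with
#'   denominator n.
#' @return A single number.
#' @examples
#' standardized_mse(c(0, 1, 2), c(0, 0, 0))  # 250
#' @export
standardized_mse <- function(y, yhat, var_y = NULL) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least 2 cases")
  if (is.null(var_y)) var_y <- mean((y - mean(y))^2)
  if (var_y <= 0) stop("response variance is zero; standardized MSE undefined")
  100 * mean((y - yhat)^2) / var_y
}

#' Normalized multiclass Brier score (x 100)
#'
#' The sum-over-classes Brier score rescaled by `J / (4 (J - 1))` and
#' multiplied by 100, the unique linear scaling under which uniform guessing
#' `p = 1/J` scores 25 for every class count J (and a perfect one-hot
#' predictor scores 0). Values near 25 therefore mean "no better than random
#' guessing" regardless of J.
#'
#' @param probs n x J row-stochastic probability matrix.
#' @param labels integer class labels `0..J-1`.
#' @param normalize if `FALSE`, return the raw `100 * mean sum (p - 1)^2`
#'   without the J-dependent factor.
#' @return A single number.
#' @export
brier_score <- function(probs, labels, normalize = TRUE) {
  probs <- as.matrix(probs)
  n <- nrow(probs); J <- ncol(probs)
  if (n != length(labels)) stop("probs and labels disagree on n")
  if (J < 2L) stop("need J >= 2 probability columns")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be nonnegative and sum to 1")
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= J)) stop("labels must lie in 0..J-1")
  onehot <- matrix(0, n, J)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  raw <- mean(rowSums((probs - onehot)^2))
  if (normalize) 100 * raw * J / (4 * (J - 1)) else 100 * raw
}

#' Score predictions for a task
#'
#' Convenience dispatcher: standardized MSE for regression, normalized Brier
#' for multiclass.
#'
#' @param data an [sf_dataset()] holding the evaluation responses.
#' @param pred predictions (vector or probability matrix).
#' @param var_y passed to [standardized_mse()].
#' @return A single number.
#' @export
score_predictions <- function(data, pred, var_y = NULL) {
  if (is_multiclass(data)) brier_score(pred, data$y)
  else standardized_mse(data$y, pred, var_y = var_y)
}
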