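#' Construct a modelling dataset
#'
#' The unit every stage of the package consumes: a numeric feature matrix, a
#' response, and a task kind. Multiclass responses are integer labels
#' `0..J-1`; every class must be present at least once.
#'
#' @param X numeric matrix (n x p) of features; categorical features must
#'   already be integer-coded (see [load_dataset()]).
#' @param y response: numeric vector (regression) or integer labels `0..J-1`
#'   (multiclass).
#' @param task `"regression"` or `"multiclass"`.
#' @return An object of class `sf_dataset` with elements `X`, `y`, `task`,
#'   `n`, `p` and (multiclass only) `J`.
#' @examples
#' d <- sf_dataset(matrix(rnorm(40), 20, 2), rnorm(20), "regression")
#' d$n; d$p
#' @export
sf_dataset <- function(X, y, task = c("regression", "multiclass")) {
  task <- match.arg(task)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 cases")
  if (ncol(X) < 1L) stop("need at least 1 feature")
  if (nrow(X) != length(y)) stop("X and y disagree on n")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite values")
  if (anyNA(y)) stop("y contains missing values")
  obj <- list(X = X, y = NULL, task = task, n = nrow(X), p = ncol(X))
  if (task == "regression") {
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("y contains non-finite values")
    obj$y <- y
  } else {
    y <- as.integer(y)
    J <- max(y) + 1L
    if (J < 2L) stop("multiclass response needs J >= 2 classes")
    if (!setequal(unique(y), 0:(J - 1L)))
      stop("multiclass labels must be 0..J-1 with every class present")
    obj$y <- y
    obj$J <- J
  }
  class(obj) <- "sf_dataset"
  obj
}

#' @export
print.sf_dataset <- function(x, ...) {
  cat(sprintf("<sf_dataset> %s: n = %d, p = %d%s\n", x$task, x$n, x$p,
              if (x$task == "multiclass") sprintf(", J = %d", x$J) else ""))
  invisible(x)
}

is_multiclass <- function(data) identical(data$task, "multiclass")
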