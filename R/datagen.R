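#' Benchmark regression surfaces
#'
#' The noiseless mean functions behind the three Friedman regression
#' benchmarks, exposed so tests and users can evaluate the signal directly.
#'
#' * #1: `10 sin(pi x1 x2) + 20 (x3 - 0.5)^2 + 10 x4 + 5 x5` on `[0,1]^10`
#'   (features 6-10 are inert).
#' * #2: `sqrt(x1^2 + (x2 x3 - 1/(x2 x4))^2)`.
#' * #3: `atan((x2 x3 - 1/(x2 x4)) / x1)`.
#'
#' @param X numeric matrix with at least 5 (#1) or exactly 4 (#2, #3) columns.
#' @return Numeric vector of surface values.
#' @export
friedman1_surface <- function(X) {
  X <- unname(rbind(X))
  10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 + 10 * X[, 4] + 5 * X[, 5]
}

#' @rdname friedman1_surface
#' @export
friedman2_surface <- function(X) {
  X <- unname(rbind(X))
  sqrt(X[, 1]^2 + (X[, 2] * X[, 3] - 1 / (X[, 2] * X[, 4]))^2)
}

#' @rdname friedman1_surface
#' @export
friedman3_surface <- function(X) {
  X <- unname(rbind(X))
  atan((X[, 2] * X[, 3] - 1 / (X[, 2] * X[, 4])) / X[, 1])
}

#' Friedman benchmark generators
#'
#' Seeded draws from the canonical Friedman regression benchmarks. #1 draws
#' `X ~ Uniform(0,1)^10` (p = 10, five inert features); #2 and #3 draw
#' `x1 ~ U(0,100)`, `x2 ~ U(40pi, 560pi)`, `x3 ~ U(0,1)`, `x4 ~ U(1,11)`
#' (p = 4). Gaussian noise is added to the surface with the canonical
#' standard deviations (1, 125 and 0.1 respectively).
#'
#' @param n sample size.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return An [sf_dataset()] with `task = "regression"`.
#' @export
gen_friedman1 <- function(n, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n * 10), n, 10)
  y <- friedman1_surface(X) + rnorm(n, sd = noise_sd)
  sf_dataset(X, y, "regression")
}

friedman23_X <- function(n) {
  cbind(runif(n, 0, 100), runif(n, 40 * pi, 560 * pi), runif(n), runif(n, 1, 11))
}

#' @rdname gen_friedman1
#' @export
gen_friedman2 <- function(n, noise_sd = 125, seed = 1L) {
  set.seed(seed)
  X <- friedman23_X(n)
  sf_dataset(X, friedman2_surface(X) + rnorm(n, sd = noise_sd), "regression")
}

#' @rdname gen_friedman1
#' @export
gen_friedman3 <- function(n, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  X <- friedman23_X(n)
  sf_dataset(X, friedman3_surface(X) + rnorm(n, sd = noise_sd), "regression")
}

#' Gaussian two-class classification benchmarks
#'
#' Balanced draws from the canonical Gaussian mixtures in d dimensions, with
#' `a = 2/sqrt(d)`:
#'
#' * `twonorm`: class 0 is `N(+a 1, I)`, class 1 is `N(-a 1, I)`; the Bayes
#'   rule is the sign of `a * sum(x)` with error `pnorm(-2)` (about 2.3%).
#' * `threenorm`: class 0 is an equal mixture of `N(+a 1, I)` and
#'   `N(-a 1, I)`; class 1 is `N((a, -a, a, -a, ...), I)`.
#' * `ringnorm`: class 0 is `N(0, 4 I)`; class 1 is `N(a' 1, I)` where `a'`
#'   defaults to `1/sqrt(d)` (the benchmark-collection convention; settable
#'   via `ringnorm_a` since sources differ).
#'
#' Class sizes are `ceiling(n/2)` and `floor(n/2)`.
#'
#' @param name one of `"twonorm"`, `"threenorm"`, `"ringnorm"`.
#' @param n sample size (>= 2).
#' @param d dimension (default 20).
#' @param seed integer seed.
#' @param ringnorm_a mean constant for the ringnorm tight class.
#' @return An [sf_dataset()] with `task = "multiclass"`, J = 2.
#' @export
gen_gaussian_classif <- function(name = c("twonorm", "threenorm", "ringnorm"),
                                 n, d = 20L, seed = 1L,
                                 ringnorm_a = 1 / sqrt(d)) {
  name <- match.arg(name)
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  n0 <- ceiling(n / 2); n1 <- n - n0
  a <- 2 / sqrt(d)
  X <- matrix(rnorm(n * d), n, d)
  i0 <- seq_len(n0); i1 <- n0 + seq_len(n1)
  if (name == "twonorm") {
    X[i0, ] <- X[i0, , drop = FALSE] + a
    X[i1, ] <- X[i1, , drop = FALSE] - a
  } else if (name == "threenorm") {
    half <- sample(c(TRUE, FALSE), n0, replace = TRUE)
    X[i0[half], ] <- X[i0[half], , drop = FALSE] + a
    X[i0[!half], ] <- X[i0[!half], , drop = FALSE] - a
    alt <- rep(c(a, -a), length.out = d)
    X[i1, ] <- sweep(X[i1, , drop = FALSE], 2, alt, "+")
  } else {
    X[i0, ] <- 2 * X[i0, , drop = FALSE]
    X[i1, ] <- X[i1, , drop = FALSE] + ringnorm_a
  }
  y <- c(rep(0L, n0), rep(1L, n1))
  sf_dataset(X, y, "multiclass")
}

#' Append inert noise features
#'
#' Adds `extra` independent `Uniform(0,1)` columns to a dataset, leaving the
#' response untouched — the "big p" variants of the benchmarks.
#'
#' @param data an [sf_dataset()].
#' @param extra number of columns to append (>= 0).
#' @param seed integer seed.
#' @return An [sf_dataset()] with `p + extra` features.
#' @export
add_noise_features <- function(data, extra, seed = 1L) {
  stopifnot(inherits(data, "sf_dataset"))
  extra <- as.integer(extra)
  if (extra < 0L) stop("extra must be >= 0")
  if (extra == 0L) return(data)
  set.seed(seed)
  sf_dataset(cbind(data$X, matrix(runif(data$n * extra), data$n, extra)),
             data$y, data$task)
}

#' Generate a named benchmark dataset
#'
#' Dispatcher over the package's generators, used by the benchmark harness
#' and the command line. Known names: `friedman1`, `friedman2`, `friedman3`,
#' `twonorm`, `threenorm`, `ringnorm`, plus a `noise` generator (pure-noise
#' response, `y ~ N(0,1)` independent of `X ~ U(0,1)^p`).
#'
#' @param name generator name.
#' @param n sample size.
#' @param seed integer seed.
#' @param extra_noise_features inert Uniform(0,1) columns to append.
#' @param noise_sd noise level override for the regression generators
#'   (`NULL` = each generator's canonical default).
#' @param p feature count for the `noise` generator (default 10).
#' @return An [sf_dataset()].
#' @export
gen_benchmark <- function(name, n, seed = 1L, extra_noise_features = 0L,
                          noise_sd = NULL, p = 10L) {
  data <- switch(name,
    friedman1 = if (is.null(noise_sd)) gen_friedman1(n, seed = seed)
                else gen_friedman1(n, noise_sd = noise_sd, seed = seed),
    friedman2 = if (is.null(noise_sd)) gen_friedman2(n, seed = seed)
                else gen_friedman2(n, noise_sd = noise_sd, seed = seed),
    friedman3 = if (is.null(noise_sd)) gen_friedman3(n, seed = seed)
                else gen_friedman3(n, noise_sd = noise_sd, seed = seed),
    twonorm = ,
    threenorm = ,
    ringnorm = gen_gaussian_classif(name, n, seed = seed),
    noise = {
      set.seed(seed)
      sf_dataset(matrix(runif(n * p), n, p), rnorm(n), "regression")
    },
    stop(sprintf("unknown generator '%s'", name)))
  if (extra_noise_features > 0L)
    data <- add_noise_features(data, extra_noise_features, seed = seed + 104729L)
  data
}
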