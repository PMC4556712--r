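#' Simulate AR(1)-autocorrelated multivariate Gaussian time series
#'
#' Draws a p x T matrix whose columns (time points) are jointly Gaussian
#' with cross-sectional covariance `Sigma` and temporal correlation
#' \eqn{\rho^{|lag|}} between columns (the Toeplitz covariance of a
#' stationary AR(1) process). The construction uses the stationary AR(1)
#' recursion \eqn{x_t = \rho x_{t-1} + \sqrt{1-\rho^2}\, \epsilon_t} applied
#' to innovations colored by a Cholesky factor of `Sigma`; this has exactly
#' the same Gaussian law as pre/post-multiplying a standard normal matrix by
#' the two Cholesky factors, but runs in O(pT) instead of O(T^3).
#'
#' @param Sigma positive-definite p x p covariance matrix.
#' @param T_len number of time points (>= 2).
#' @param rho AR(1) autoregressive parameter, |rho| < 1 (default 0.5).
#' @param seed integer RNG seed; fully determines the output.
#' @return a `time_series_matrix`: p x T numeric matrix with attributes
#'   `rho` and `seed`.
#' @export
simulate_ar1_gaussian <- function(Sigma, T_len, rho = 0.5, seed = 1L) {
  stopifnot(is.matrix(Sigma), nrow(Sigma) == ncol(Sigma))
  if (!is_count(T_len, min = 2L))
    stop_invalid("`T_len` must be an integer >= 2")
  if (!is.numeric(rho) || abs(rho) >= 1)
    stop_invalid("`rho` must satisfy |rho| < 1")
  L <- tryCatch(chol(Sigma), error = function(e)
    stop_invalid("`Sigma` is not positive definite: ", conditionMessage(e)))
  p <- nrow(Sigma)
  Z <- with_seed(seed, matrix(rnorm(p * T_len), nrow = p))
  X <- matrix(0, p, T_len)
  X[, 1L] <- Z[, 1L]
  if (T_len > 1L) {
    fac <- sqrt(1 - rho^2)
    for (t in 2:T_len) X[, t] <- rho * X[, t - 1L] + fac * Z[, t]
  }
  Y <- crossprod(L, X)  # t(chol(Sigma)) %*% X colors the cross-section
  structure(Y, rho = rho, seed = as.integer(seed),
            class = c("time_series_matrix", "matrix", "array"))
}

#' @export
print.time_series_matrix <- function(x, ...) {
  cat(sprintf("<time_series_matrix> %d nodes x %d time points (rho = %g)\n",
              nrow(x), ncol(x), attr(x, "rho")))
  invisible(x)
}

#' Nested prefix subsets of a time series
#'
#' @param ts a `time_series_matrix` (or any p x T matrix).
#' @param lengths vector of prefix lengths, each at most `ncol(ts)`.
#' @return list of `time_series_matrix` objects; element k holds the first
#'   `lengths[k]` time points, so shorter subsets are prefixes of longer
#'   ones.
#' @export
nested_subsets <- function(ts, lengths) {
  stopifnot(is.matrix(ts))
  if (any(lengths > ncol(ts)) || any(lengths < 1L))
    stop_invalid("prefix lengths must be in [1, ncol(ts)]")
  lapply(lengths, function(L) {
    structure(ts[, seq_len(L), drop = FALSE],
              rho = attr(ts, "rho"), seed = attr(ts, "seed"),
              class = c("time_series_matrix", "matrix", "array"))
  })
}

#' Effective sample size of AR(1)-correlated observations
#'
#' Autocorrelated observations carry less information than independent
#' ones; for an AR(1) process with parameter rho the equivalent number of
#' independent observations is \eqn{n' = n (1 - \rho) / (1 + \rho)}.
#'
#' @param n number of observations (>= 1).
#' @param rho AR(1) parameter, |rho| < 1.
#' @return the effective sample size n'.
#' @export
effective_sample_size <- function(n, rho) {
  if (!is.numeric(n) || any(n < 1)) stop_invalid("`n` must be >= 1")
  if (!is.numeric(rho) || any(abs(rho) >= 1))
    stop_invalid("`rho` must satisfy |rho| < 1")
  n * (1 - rho) / (1 + rho)
}
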