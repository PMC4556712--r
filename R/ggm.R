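#' Sample partial-correlation edge weights on a topology
#'
#' Fills the support of `topology` with weights drawn uniformly from
#' \eqn{[-1, -0.01] \cup [0.01, 1]} (signs equiprobable, magnitudes uniform
#' and bounded away from zero), ones on the diagonal and exact zeros on
#' non-edges. The result is a candidate partial-correlation matrix that is
#' generally not yet positive definite; see [regularize_to_pd()].
#'
#' @param topology a `network_topology`.
#' @param seed integer RNG seed.
#' @return p x p symmetric numeric matrix with unit diagonal.
#' @export
sample_edge_weights <- function(topology, seed = 1L) {
  stopifnot(inherits(topology, "network_topology"))
  p <- topology$n_nodes
  R <- diag(p)
  e <- topology$edges
  if (nrow(e) > 0L) {
    w <- with_seed(seed, {
      mag <- runif(nrow(e), 0.01, 1)
      sgn <- sample(c(-1, 1), nrow(e), replace = TRUE)
      mag * sgn
    })
    R[cbind(e[, 1L], e[, 2L])] <- w
    R[cbind(e[, 2L], e[, 1L])] <- w
  }
  R
}

# concentration matrix implied by a unit-diagonal partial correlation matrix
# (unit partial variances): gamma_ij = -r_ij off-diagonal, 1 on the diagonal
pcor_to_concentration <- function(R) {
  K <- -R
  diag(K) <- 1
  K
}

#' Shrink edge weights until the partial-correlation matrix is valid
#'
#' A raw weight matrix from [sample_edge_weights()] usually does not
#' correspond to a positive-definite concentration matrix. All off-diagonal
#' entries are multiplied by a common factor `c` in (0, 1], chosen by
#' bisection as (close to) the largest factor for which the implied
#' concentration matrix has minimum eigenvalue at least `eig_floor`.
#' Uniform scaling preserves the zero pattern and the signs exactly, so
#' re-zeroing non-edges afterwards is a no-op; it is still applied for
#' numeric hygiene.
#'
#' @param raw p x p symmetric matrix with unit diagonal whose support equals
#'   the topology.
#' @param topology the `network_topology` defining the support.
#' @param eig_floor required minimum eigenvalue of the implied concentration
#'   matrix. The default 1e-3 keeps the model near the just-barely-PD
#'   construction (so indirect correlations stay strong enough to confound
#'   the pairwise estimator, the phenomenon under study) while keeping the
#'   implied covariance numerically invertible; see the methods vignette.
#' @param tol bisection tolerance on the scale factor (default 1e-4).
#' @return a positive-definite partial-correlation matrix with the same
#'   support; the scale factor is attached as attribute `"shrink_factor"`.
#' @export
regularize_to_pd <- function(raw, topology, eig_floor = 1e-3, tol = 1e-4) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw),
            inherits(topology, "network_topology"),
            nrow(raw) == topology$n_nodes)
  if (max(abs(raw - t(raw))) > 1e-12) stop_invalid("`raw` must be symmetric")
  p <- nrow(raw)
  # eigenvalues of the concentration matrix at factor c are 1 + c * ev,
  # where ev are the eigenvalues of the off-diagonal part of -raw
  A <- pcor_to_concentration(raw)
  diag(A) <- 0
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev_min <- min(ev)
  scale_ok <- function(c) 1 + c * ev_min >= eig_floor
  if (scale_ok(1)) {
    cc <- 1
  } else {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (scale_ok(mid)) lo <- mid else hi <- mid
    }
    cc <- lo
  }
  if (cc <= 0)
    stop_invalid("regularization failed: no positive scale factor ",
                 "reaches minimum eigenvalue ", eig_floor,
                 " (min eigenvalue of off-diagonal part: ", ev_min, ")")
  R <- raw
  R[upper.tri(R) | lower.tri(R)] <- cc * R[upper.tri(R) | lower.tri(R)]
  # exact zeros off the support (no-op under uniform scaling)
  mask <- matrix(FALSE, p, p)
  e <- topology$edges
  if (nrow(e) > 0L) {
    mask[cbind(e[, 1L], e[, 2L])] <- TRUE
    mask[cbind(e[, 2L], e[, 1L])] <- TRUE
  }
  R[!mask & row(R) != col(R)] <- 0
  attr(R, "shrink_factor") <- cc
  R
}

#' Implied correlation matrix of a partial-correlation matrix
#'
#' Negates the off-diagonal partial correlations to obtain the (unit
#' partial variance) concentration matrix, inverts it, and standardizes to
#' a correlation matrix. For a positive-definite concentration matrix the
#' inverse and the Moore-Penrose pseudoinverse coincide; an SVD
#' pseudoinverse is used as fallback if plain inversion fails.
#'
#' @param R positive-definite partial-correlation matrix (unit diagonal).
#' @return correlation matrix C with unit diagonal.
#' @export
pcor_to_cor <- function(R) {
  K <- pcor_to_concentration(R)
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop_invalid("implied concentration matrix is not positive definite ",
                 "(min eigenvalue ", signif(ev_min, 4),
                 "); regularize first")
  Sgm <- tryCatch(solve(K), error = function(e) pseudo_inverse(K))
  stats::cov2cor(Sgm)
}

#' Partial correlations implied by a correlation/covariance matrix
#'
#' Inverse operation of [pcor_to_cor()]: inverts `C` and rescales the
#' negated off-diagonal of the resulting concentration matrix.
#'
#' @param C positive-definite correlation or covariance matrix.
#' @return partial-correlation matrix with unit diagonal.
#' @export
cor_to_pcor <- function(C) {
  concentration_to_pcor(solve(C))
}

#' Scale a correlation matrix to a covariance matrix
#'
#' @param C valid correlation matrix.
#' @param variance common variance of all nodes (default 2, the benchmark's
#'   data-generating value).
#' @return covariance matrix `variance * C`.
#' @export
scale_to_covariance <- function(C, variance = 2) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0)
    stop_invalid("`variance` must be a positive number")
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop_invalid("`C` must have unit diagonal")
  variance * C
}

#' Build a complete Gaussian graphical model on a topology
#'
#' Convenience wrapper: sample weights, regularize to positive definiteness,
#' and derive the implied correlation and covariance matrices.
#'
#' @inheritParams sample_edge_weights
#' @param variance common node variance of the covariance matrix.
#' @return list with elements `pcor` (true partial-correlation matrix R),
#'   `cor` (implied correlation matrix C), `sigma` (covariance matrix),
#'   `topology`, `seed` and `shrink_factor`.
#' @export
build_ggm <- function(topology, seed = 1L, variance = 2) {
  raw <- sample_edge_weights(topology, seed)
  R <- regularize_to_pd(raw, topology)
  C <- pcor_to_cor(R)
  list(pcor = R, cor = C, sigma = scale_to_covariance(C, variance),
       topology = topology, seed = seed,
       shrink_factor = attr(R, "shrink_factor"))
}

# Moore-Penrose pseudoinverse by SVD with the standard relative cutoff
pseudo_inverse <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) stop_invalid("matrix has rank zero")
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}
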