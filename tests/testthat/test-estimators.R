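test_that("sample_covariance uses the n-1 denominator", {
  x <- matrix(c(0, 0, 2, 2), nrow = 2)   # two observations (0,0), (2,2)
  expect_equal(sample_covariance(x), matrix(2, 2, 2))
  expect_equal(sample_covariance(matrix(5, 3, 10)), matrix(0, 3, 3))
  set.seed(1)
  y <- matrix(rnorm(5 * 50), 5, 50)
  expect_equal(sample_covariance(y), oracle_cov(y), tolerance = 1e-12)
  expect_error(sample_covariance(matrix(1, 3, 1)), "2 time points")
})

test_that("pearson_correlation matches S_ij / sqrt(S_ii S_jj)", {
  set.seed(2)
  x <- matrix(rnorm(4 * 100), 4, 100)
  x[2, ] <- x[1, ]                      # duplicated node
  w <- pearson_correlation(x)
  expect_identical(w$method, "pairwise")
  expect_equal(w$values[1, 2], 1)
  S <- sample_covariance(x)
  expect_equal(w$values, S / sqrt(outer(diag(S), diag(S))),
               tolerance = 1e-12)
  long <- matrix(rnorm(2 * 20000), 2, 20000)
  expect_lt(abs(pearson_correlation(long)$values[1, 2]), 0.03)
  x[3, ] <- 7
  expect_error(pearson_correlation(x), "zero variance.*3")
})

test_that("concentration_to_pcor implements the scaled negation", {
  expect_equal(concentration_to_pcor(diag(c(2, 3, 4))), diag(3))
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- -0.5
  G[2, 3] <- G[3, 2] <- -0.5
  P <- concentration_to_pcor(G)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[1, 3], 0)
  expect_equal(concentration_to_pcor(7 * G), P)   # scale invariance
  G[1, 1] <- -1
  expect_error(concentration_to_pcor(G), "non-positive diagonal")
})

test_that("Eq-2 round trip recovers the true partial correlations", {
  topo <- finalize_connected(generate_random(25, count = 40, seed = 4))
  R <- regularize_to_pd(sample_edge_weights(topo, seed = 5), topo)
  K <- -unclass(R); diag(K) <- 1
  expect_equal(concentration_to_pcor(K), unclass(R), ignore_attr = TRUE)
})

test_that("shrinkage limits: lambda 1 kills all edges, lambda 0 is the
           plain inverse", {
  topo <- finalize_connected(generate_random(15, count = 25, seed = 6))
  ts <- simulate_ar1_gaussian(build_ggm(topo, seed = 7)$sigma, 4000,
                              0.5, seed = 8)
  w1 <- shrinkage_pcor(ts, lambda = 1)
  expect_equal(w1$values, diag(topo$n_nodes))
  w0 <- shrinkage_pcor(ts, lambda = 0)
  S <- sample_covariance(ts)
  expect_equal(w0$values, concentration_to_pcor(solve(S)),
               tolerance = 1e-10)
  west <- shrinkage_pcor(ts)
  expect_true(west$tuning$lambda_s >= 0 && west$tuning$lambda_s <= 1)
})

test_that("shrinkage is defined and PD-safe for n < p", {
  set.seed(9)
  x <- matrix(rnorm(30 * 10), 30, 10)    # p = 30 nodes, n = 10
  w <- shrinkage_pcor(x)
  expect_true(all(is.finite(w$values)))
  expect_true(isSymmetric(w$values, tol = 1e-12))
})

test_that("pseudoinverse estimator matches the inverse when S is PD", {
  topo <- finalize_connected(generate_random(12, count = 20, seed = 10))
  ts <- simulate_ar1_gaussian(build_ggm(topo, seed = 11)$sigma, 5000,
                              0.5, seed = 12)
  S <- sample_covariance(ts)
  w <- pseudoinverse_pcor(ts)
  expect_equal(w$values, concentration_to_pcor(solve(S)),
               tolerance = 1e-8)
})

test_that("pseudoinverse satisfies the Moore-Penrose axioms", {
  skip_if_not_installed("MASS")
  for (s in 1:5) {
    set.seed(s)
    # rank-deficient PSD matrix
    B <- matrix(rnorm(10 * 4), 10, 4)
    S <- tcrossprod(B)
    Sp <- ggmbench:::pseudo_inverse(S)
    expect_equal(S %*% Sp %*% S, S, tolerance = 1e-8)
    expect_equal(Sp %*% S %*% Sp, Sp, tolerance = 1e-8)
    expect_equal(Sp, MASS::ginv(S), tolerance = 1e-6)
  }
  # n < p input gives a finite symmetric weight matrix
  set.seed(6)
  x <- matrix(rnorm(20 * 8), 20, 8)
  w <- pseudoinverse_pcor(x)
  expect_true(all(is.finite(w$values)))
  expect_true(isSymmetric(w$values, tol = 1e-8))
  expect_error(pseudoinverse_pcor(matrix(0, 3, 5)), "zero")
})

test_that("glasso limits: heavy penalty empties the support, zero penalty
           matches the inverse", {
  topo <- finalize_connected(generate_random(10, count = 16, seed = 13))
  ts <- simulate_ar1_gaussian(build_ggm(topo, seed = 14)$sigma, 4000,
                              0.5, seed = 15)
  S <- sample_covariance(ts)
  C <- cov2cor(S)
  heavy <- glasso_fit(C, 10)
  expect_identical(sum(heavy$support), 0)
  off <- row(C) != col(C)
  expect_true(all(heavy$wi[off] == 0))

  f0 <- glasso_fit(C, 0, tol = 1e-8)
  expect_equal(f0$wi, solve(C), tolerance = 1e-4)
  w0 <- glasso_pcor(ts, lambda = 0)
  expect_equal(w0$values, concentration_to_pcor(solve(C)),
               tolerance = 1e-4)
})

test_that("glasso solutions satisfy the KKT optimality conditions", {
  set.seed(16)
  X <- matrix(rnorm(300 * 12), 300, 12) %*% matrix(rnorm(144), 12) / 4
  C <- cov2cor(cov(X))
  for (lam in c(0.3, 0.05)) {
    f <- glasso_fit(C, lam, tol = 1e-6)
    W <- f$w; Th <- f$wi
    expect_equal(solve(Th), W, tolerance = 1e-6)
    D <- W - C
    off <- row(C) != col(C)
    expect_lte(max(abs(D[off])), lam + 1e-6)
    nz <- off & Th != 0
    expect_lt(max(abs(D[nz] - lam * sign(Th[nz]))), 1e-6)
    expect_equal(diag(W), diag(C) + lam)
  }
})

test_that("glasso density targeting hits the requested support size", {
  topo <- finalize_connected(generate_random(40, count = 100, seed = 17))
  ts <- simulate_ar1_gaussian(build_ggm(topo, seed = 18)$sigma, 800,
                              0.5, seed = 19)
  for (target in c(60, 150, 400)) {
    w <- glasso_pcor(ts, target_edges = target)
    got <- w$tuning$n_edges
    expect_lte(abs(got - target), max(1, round(0.02 * target)) + 3)
    expect_identical(sum(w$values[upper.tri(w$values)] != 0), as.integer(got))
  }
  expect_error(glasso_pcor(ts, target_edges = 1e6), "target_edges")
})

test_that("estimators are symmetric and equivariant under node relabeling", {
  topo <- finalize_connected(generate_random(12, count = 20, seed = 20))
  ts <- simulate_ar1_gaussian(build_ggm(topo, seed = 21)$sigma, 300,
                              0.5, seed = 22)
  set.seed(23)
  perm <- sample(nrow(ts))
  for (m in c("pairwise", "shrinkage", "pseudoinverse", "glasso")) {
    w <- estimate_weights(ts, m, target_edges = 20)
    expect_true(isSymmetric(w$values, tol = 1e-10))
    wp <- estimate_weights(unclass(ts)[perm, ], m, target_edges = 20)
    # glasso gets a looser tolerance: coordinate-descent sweep order
    # depends on the labeling
    expect_equal(wp$values, w$values[perm, perm],
                 tolerance = if (m == "glasso") 5e-3 else 1e-8)
  }
})

test_that("partial-correlation estimators beat pairwise correlation at
           matched density", {
  tpr_by_method <- sapply(1:10, function(s) {
    topo <- finalize_connected(generate_random(30, count = 45, seed = s * 11))
    ggm <- build_ggm(topo, seed = s * 13)
    ts <- simulate_ar1_gaussian(ggm$sigma, 5000, 0.5, seed = s * 17)
    k <- n_edges(topo)
    sapply(c("pairwise", "shrinkage", "pseudoinverse", "glasso"),
           function(m) {
      w <- estimate_weights(ts, m,
                            target_edges = glasso_support_target(
                              k, topo$n_nodes))
      tpr_fpr(select_top_k(w, k), topo)$tpr
    })
  })
  means <- rowMeans(tpr_by_method)
  expect_gt(means["shrinkage"], means["pairwise"])
  expect_gt(means["pseudoinverse"], means["pairwise"])
  expect_gt(means["glasso"], means["pairwise"])
})
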