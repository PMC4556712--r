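# Brute-force reference implementations, independent of the package's code
# paths (and of igraph): used to cross-check the graph metrics and the
# estimator algebra on small inputs.

topo_to_adj <- function(x) {
  A <- matrix(0L, x$n_nodes, x$n_nodes)
  e <- x$edges
  if (nrow(e) > 0L) {
    A[cbind(e[, 1L], e[, 2L])] <- 1L
    A[cbind(e[, 2L], e[, 1L])] <- 1L
  }
  A
}

rand_topology <- function(n, p_edge, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  network_topology(n, pairs[keep, , drop = FALSE])
}

# all-pairs shortest-path distances by Floyd-Warshall
oracle_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

oracle_apl <- function(A) {
  D <- oracle_dist(A)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  mean(d)
}

oracle_triangles <- function(A) {
  sum(diag(A %*% A %*% A)) / 6
}

oracle_transitivity <- function(A) {
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(NaN)
  3 * oracle_triangles(A) / triples
}

oracle_local_transitivity <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < 2L) return(NA_real_)
    sub <- A[nb, nb, drop = FALSE]
    sum(sub) / (length(nb) * (length(nb) - 1))
  })
}

oracle_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1L))))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  list(n_components = cur, largest_size = max(tabulate(comp)),
       membership = comp)
}

# betweenness with fractional credit, via geodesic counting on the distance
# matrix: sigma_st(v) = sigma_sv * sigma_vt when v lies on a geodesic
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  # geodesic counts by dynamic programming over distance layers
  S <- matrix(0, n, n)
  diag(S) <- 1
  maxd <- max(D[is.finite(D)])
  for (d in seq_len(max(1, maxd))) {
    idx <- which(D == d, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1L]; t <- idx[r, 2L]
      pred <- which(A[, t] == 1L & D[s, ] == d - 1)
      S[s, t] <- sum(S[s, pred])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  btw
}

oracle_cov <- function(x) {
  # x: p x T, observations in columns; naive double loop
  p <- nrow(x); n <- ncol(x)
  xb <- rowMeans(x)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    S[i, j] <- sum((x[i, ] - xb[i]) * (x[j, ] - xb[j])) / (n - 1)
  S
}

# the explicit O(T^3) time-series construction: color a standard normal
# matrix by t(chol(Sigma)) on the left and chol(AR1-Toeplitz) on the right
oracle_ar1_series <- function(Sigma, T_len, rho, seed) {
  set.seed(seed)
  p <- nrow(Sigma)
  Z <- matrix(rnorm(p * T_len), p, T_len)
  Tpl <- stats::toeplitz(rho^(0:(T_len - 1)))
  t(chol(Sigma)) %*% Z %*% chol(Tpl)
}

lag1_autocor <- function(x) {
  mean(sapply(seq_len(nrow(x)), function(i)
    cor(x[i, -ncol(x)], x[i, -1L])))
}

# random tree on n nodes: each new node attaches to a uniform earlier node
rand_tree <- function(n, seed) {
  set.seed(seed)
  parents <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  network_topology(n, cbind(parents, 2:n))
}

pair_keys_for_test <- function(edges) {
  if (length(edges) == 0L) return(character(0))
  paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
}
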