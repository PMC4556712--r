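as_bn <- function(topo) binary_network(topo$n_nodes, topo$edges)

test_that("tpr_fpr counts hits and false alarms", {
  truth <- network_topology(4, rbind(c(1, 2), c(2, 3)))
  est <- binary_network(4, rbind(c(1, 2), c(3, 4)))
  r <- tpr_fpr(est, truth)
  expect_equal(r$tpr, 0.5)
  expect_equal(r$fpr, 1 / 4)

  perfect <- tpr_fpr(as_bn(truth), truth)
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)

  all_pairs <- t(combn(4, 2))
  compl <- all_pairs[!pair_keys_for_test(all_pairs) %in%
                       pair_keys_for_test(truth$edges), , drop = FALSE]
  r2 <- tpr_fpr(binary_network(4, compl), truth)
  expect_equal(r2$tpr, 0)
  expect_equal(r2$fpr, 1)

  expect_error(tpr_fpr(binary_network(5, rbind(c(1, 2))), truth),
               "node sets")
})

test_that("degree bins: hub bin exact, remainder near-equal, index
           tie-break", {
  topo <- finalize_connected(generate_random(300, count = 900, seed = 1))
  bins <- assign_degree_bins(topo, top_n = 50)
  tab <- tabulate(bins$bin_assignment, 6)
  expect_identical(tab[6], 50L)
  expect_lte(diff(range(tab[1:5])), 1L)
  deg <- igraph::degree(as_igraph(topo))
  expect_gte(min(deg[bins$bin_assignment == 6]),
             max(deg[bins$bin_assignment == 1]))

  # 12 nodes, top 2: all bins of size 2
  topo12 <- path_net_12 <- network_topology(12, cbind(1:11, 2:12))
  bins12 <- assign_degree_bins(topo12, top_n = 2)
  expect_identical(tabulate(bins12$bin_assignment, 6), rep(2L, 6))

  # equal degrees: assignment determined by index
  ring <- network_topology(12, rbind(cbind(1:11, 2:12), c(1, 12)))
  bins_r <- assign_degree_bins(ring, top_n = 2)
  expect_identical(bins_r$bin_assignment,
                   c(6L, 6L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_error(assign_degree_bins(ring, top_n = 12), "top_n")
})

test_that("binned rates match exhaustive enumeration", {
  set.seed(2)
  truth <- rand_topology(12, 0.35, seed = 3)
  est <- rand_topology(12, 0.3, seed = 4)
  bins <- assign_degree_bins(truth, top_n = 2)
  got <- binned_tpr_fpr(as_bn(est), truth, bins)

  b <- bins$bin_assignment
  tk <- pair_keys_for_test(truth$edges)
  ek <- pair_keys_for_test(est$edges)
  for (a in 1:6) for (bb in a:6) {
    pairs <- t(combn(12, 2))
    sel <- (pmin(b[pairs[, 1]], b[pairs[, 2]]) == a &
              pmax(b[pairs[, 1]], b[pairs[, 2]]) == bb)
    pk <- pair_keys_for_test(pairs[sel, , drop = FALSE])
    n_true <- sum(pk %in% tk)
    n_tp <- sum(pk %in% tk & pk %in% ek)
    n_fp <- sum(!(pk %in% tk) & pk %in% ek)
    n_non <- length(pk) - n_true
    exp_tpr <- if (n_true > 0) n_tp / n_true else NA_real_
    exp_fpr <- if (n_non > 0) n_fp / n_non else NA_real_
    expect_equal(got$tpr_by_binpair[a, bb], exp_tpr, ignore_attr = TRUE)
    expect_equal(got$fpr_by_binpair[a, bb], exp_fpr, ignore_attr = TRUE)
    expect_equal(got$tpr_by_binpair[bb, a], got$tpr_by_binpair[a, bb],
                 ignore_attr = TRUE)
  }

  # perfect recovery: all defined TPR 1, FPR 0
  perf <- binned_tpr_fpr(as_bn(truth), truth, bins)
  expect_true(all(perf$tpr_by_binpair == 1, na.rm = TRUE))
  expect_true(all(perf$fpr_by_binpair == 0, na.rm = TRUE))
})

test_that("dropping exactly the hub-hub edges zeroes TPR(6,6) only", {
  # clique of 10 hubs plus 50 pendant nodes: the clique members are the
  # highest-degree nodes, so bin 6 is exactly the clique
  clique <- t(combn(10, 2))
  pendants <- cbind(11:60, rep(1:10, 5))
  truth <- network_topology(60, rbind(clique, pendants))
  bins <- assign_degree_bins(truth, top_n = 10)
  expect_identical(which(bins$bin_assignment == 6L), 1:10)
  b <- bins$bin_assignment
  hubhub <- b[truth$edges[, 1]] == 6L & b[truth$edges[, 2]] == 6L
  expect_identical(sum(hubhub), 45L)
  est <- binary_network(truth$n_nodes, truth$edges[!hubhub, , drop = FALSE])
  got <- binned_tpr_fpr(est, truth, bins)
  expect_equal(got$tpr_by_binpair[6, 6], 0, ignore_attr = TRUE)
  others <- got$tpr_by_binpair
  others[6, 6] <- NA
  expect_true(all(others == 1, na.rm = TRUE))
})

test_that("binned true-edge counts aggregate to the overall TPR", {
  truth <- finalize_connected(generate_random(80, count = 300, seed = 6))
  ggm <- build_ggm(truth, seed = 7)
  ts <- simulate_ar1_gaussian(ggm$sigma, 200, 0.5, seed = 8)
  est <- select_top_k(shrinkage_pcor(ts), n_edges(truth))
  bins <- assign_degree_bins(truth, top_n = 10)
  got <- binned_tpr_fpr(est, truth, bins)
  overall <- tpr_fpr(est, truth)

  b <- bins$bin_assignment
  ba <- pmin(b[truth$edges[, 1]], b[truth$edges[, 2]])
  bb <- pmax(b[truth$edges[, 1]], b[truth$edges[, 2]])
  n_true <- matrix(0, 6, 6)
  for (r in seq_along(ba)) n_true[ba[r], bb[r]] <- n_true[ba[r], bb[r]] + 1
  ut <- upper.tri(n_true, diag = TRUE)
  w <- n_true[ut]
  t_binned <- got$tpr_by_binpair[ut]
  expect_equal(sum(w * t_binned, na.rm = TRUE) / sum(w), overall$tpr)
})

test_that("normalized_node_diff uses the true-variable range", {
  expect_equal(normalized_node_diff(c(3, 7), c(3, 7)), 0)
  expect_equal(normalized_node_diff(c(5, 10), c(0, 10)), 0.5)
  # transform anchors: min(true) -> 0, max(true) -> 1
  true <- c(2, 4, 10)
  est <- c(10, 2, 2)
  expect_equal(normalized_node_diff(est, true),
               abs(1 - 0) + abs(0 - 0.25) + abs(0 - 1))
  expect_error(normalized_node_diff(c(1, 2), c(5, 5)), "constant")
  expect_error(normalized_node_diff(1:3, 1:2), "equal length")
})

test_that("fpr_transform is exp(-100 x)", {
  expect_equal(fpr_transform(0), 1)
  expect_equal(fpr_transform(0.01), exp(-1))
  x <- seq(0, 1, length.out = 50)
  expect_true(all(diff(fpr_transform(x)) < 0))
  expect_error(fpr_transform(1.2), "\\[0, 1\\]")
})

test_that("edge_overlap is the shared-edge proportion at matched density", {
  a <- binary_network(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(edge_overlap(a, a), 1)
  b <- binary_network(6, rbind(c(1, 2), c(2, 3), c(1, 6), c(5, 6)))
  expect_equal(edge_overlap(a, b), 0.5)
  expect_equal(edge_overlap(b, a), 0.5)   # symmetric
  disj <- binary_network(6, rbind(c(1, 3), c(1, 4), c(1, 5), c(1, 6)))
  expect_equal(edge_overlap(a, disj), 0)
  expect_error(edge_overlap(a, binary_network(6, rbind(c(1, 2)))),
               "matched densities")
})

test_that("area connectivity across parcellation levels", {
  # 3 coarse areas; areas 1 (fine nodes 1-2) and 2 (3-4) split, area 3 (5)
  # not split
  mapping <- c(1L, 1L, 2L, 2L, 3L)
  coarse <- binary_network(3, rbind(c(1, 2), c(2, 3)))
  fine <- binary_network(5, rbind(c(1, 2), c(2, 3)))
  ac <- area_connectivity(coarse, fine, mapping)
  expect_equal(ac$within, 0.5)    # area 1 internally wired, area 2 not
  expect_equal(ac$between, 0.5)   # pair (1,2) spanned, pair (2,3) not

  full <- binary_network(5, rbind(c(1, 2), c(3, 4)))
  expect_equal(area_connectivity(coarse, full, mapping)$within, 1)
  none <- binary_network(5, NULL)
  ac0 <- area_connectivity(coarse, none, mapping)
  expect_equal(ac0$within, 0)
  expect_equal(ac0$between, 0)
  no_coarse <- binary_network(3, NULL)
  expect_true(is.na(area_connectivity(no_coarse, fine, mapping)$between))
  expect_error(area_connectivity(coarse, fine, c(1L, 2L)), "cover")
})

test_that("recovery_report assembles rates and metric discrepancies", {
  truth <- finalize_connected(generate_random(40, count = 90, seed = 9))
  ggm <- build_ggm(truth, seed = 10)
  ts <- simulate_ar1_gaussian(ggm$sigma, 400, 0.5, seed = 11)
  w <- shrinkage_pcor(ts)
  est <- select_top_k(w, n_edges(truth))
  rep_out <- recovery_report(est, truth, weights = w,
                             reference_seeds = 1:3)
  expect_s3_class(rep_out, "recovery_report")
  expect_true(rep_out$tpr >= 0 && rep_out$tpr <= 1)
  expect_true(rep_out$fpr >= 0 && rep_out$fpr <= 1)
  expect_identical(dim(rep_out$tpr_by_binpair), c(6L, 6L))
  expect_true(all(rep_out$metric_abs_diff >= 0, na.rm = TRUE))
})
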