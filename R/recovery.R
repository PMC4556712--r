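#' True- and false-positive rates of an estimated network
#'
#' TPR is the fraction of true edges recovered; FPR is the fraction of true
#' non-edges (among all p(p-1)/2 possible pairs) declared edges.
#'
#' @param estimated a `binary_network`.
#' @param truth a `network_topology` (or `binary_network`) on the same node
#'   set.
#' @return list with `tpr` and `fpr`.
#' @export
tpr_fpr <- function(estimated, truth) {
  if (estimated$n_nodes != truth$n_nodes)
    stop_invalid("estimated and true networks have different node sets")
  p <- truth$n_nodes
  total <- p * (p - 1) / 2
  true_keys <- pair_keys(truth$edges)
  est_keys <- pair_keys(estimated$edges)
  tp <- sum(est_keys %in% true_keys)
  fp <- length(est_keys) - tp
  n_true <- length(true_keys)
  list(tpr = if (n_true > 0) tp / n_true else NA_real_,
       fpr = if (total - n_true > 0) fp / (total - n_true) else NA_real_)
}

#' Degree-based node bins
#'
#' Splits nodes into 6 bins by true degree: the `top_n` highest-degree
#' nodes (the hubs) form bin 6; the rest are sorted by degree and divided
#' into 5 near-equal bins (bin 1 = lowest degrees). Ties are broken by node
#' index; when the sizes cannot be exactly equal, the extra nodes go to the
#' lowest bins.
#'
#' @param truth a `network_topology`.
#' @param top_n size of the top bin (default 50); must be smaller than the
#'   node count.
#' @return list of class `degree_bin_spec` with per-node `bin_assignment`
#'   (1..6) and `top_bin_size`.
#' @export
assign_degree_bins <- function(truth, top_n = 50L) {
  p <- truth$n_nodes
  if (!is_count(top_n, min = 1L) || top_n >= p)
    stop_invalid("`top_n` must be in [1, n_nodes)")
  deg <- igraph::degree(as_igraph(truth))
  ord <- order(-deg, seq_len(p))          # degree desc, index asc
  bins <- integer(p)
  bins[ord[seq_len(top_n)]] <- 6L
  rest <- sort(ord[(top_n + 1L):p])       # remaining nodes
  rest <- rest[order(deg[rest], rest)]    # degree asc, index asc
  r <- length(rest)
  base <- r %/% 5L
  extra <- r %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, extra), rep(0L, 5L - extra))
  bins[rest] <- rep(1:5, times = sizes)
  structure(list(bin_assignment = bins, top_bin_size = as.integer(top_n)),
            class = "degree_bin_spec")
}

#' TPR/FPR for every pairing of degree bins
#'
#' Rates as in [tpr_fpr()], restricted to node pairs whose endpoints fall
#' in bins (a, b). Pairings without true edges (TPR) or without non-edges
#' (FPR) are reported as `NA` rather than 0.
#'
#' @inheritParams tpr_fpr
#' @param bins a `degree_bin_spec` from [assign_degree_bins()].
#' @return list with 6 x 6 symmetric matrices `tpr_by_binpair` and
#'   `fpr_by_binpair`.
#' @export
binned_tpr_fpr <- function(estimated, truth, bins) {
  if (estimated$n_nodes != truth$n_nodes)
    stop_invalid("estimated and true networks have different node sets")
  stopifnot(inherits(bins, "degree_bin_spec"))
  b <- bins$bin_assignment
  nb <- 6L
  bin_sizes <- tabulate(b, nbins = nb)

  pair_counts <- function(edges) {
    m <- matrix(0, nb, nb)
    if (nrow(edges) > 0L) {
      ba <- pmin(b[edges[, 1L]], b[edges[, 2L]])
      bb <- pmax(b[edges[, 1L]], b[edges[, 2L]])
      t <- table(factor(ba, levels = 1:nb), factor(bb, levels = 1:nb))
      m <- m + unclass(t)
    }
    m + t(m) - diag(diag(m))
  }

  true_keys <- pair_keys(truth$edges)
  est_keys <- pair_keys(estimated$edges)
  tp_edges <- estimated$edges[est_keys %in% true_keys, , drop = FALSE]
  fp_edges <- estimated$edges[!est_keys %in% true_keys, , drop = FALSE]

  n_true <- pair_counts(truth$edges)
  n_tp <- pair_counts(tp_edges)
  n_fp <- pair_counts(fp_edges)
  # total possible pairs per bin pairing
  n_tot <- outer(bin_sizes, bin_sizes)
  diag(n_tot) <- bin_sizes * (bin_sizes - 1) / 2
  n_non <- n_tot - n_true

  tpr <- ifelse(n_true > 0, n_tp / n_true, NA_real_)
  fpr <- ifelse(n_non > 0, n_fp / n_non, NA_real_)
  dimnames(tpr) <- dimnames(fpr) <- list(paste0("bin", 1:6),
                                         paste0("bin", 1:6))
  list(tpr_by_binpair = tpr, fpr_by_binpair = fpr)
}

#' Scaled sum of absolute node-metric differences
#'
#' Both vectors are linearly transformed by the range of the *true* vector
#' (true minimum maps to 0, true maximum to 1) and the sum of absolute
#' elementwise differences is returned, making per-node metrics with
#' different scales comparable.
#'
#' @param estimated_values per-node metric values of the estimated network.
#' @param true_values per-node metric values of the true network; must not
#'   be constant.
#' @return non-negative scalar.
#' @export
normalized_node_diff <- function(estimated_values, true_values) {
  if (length(estimated_values) != length(true_values))
    stop_invalid("vectors must have equal length")
  lo <- min(true_values)
  hi <- max(true_values)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop_invalid("true values are constant; normalization undefined")
  sum(abs((estimated_values - lo) / (hi - lo) - (true_values - lo) / (hi - lo)))
}

#' Exponential false-positive-rate score
#'
#' Maps an FPR to \eqn{f(FPR) = \exp(-100 \cdot FPR)}: 1 for a perfect FPR
#' of 0, decaying rapidly, so that small FPR differences at sparse
#' densities remain visible.
#'
#' @param fpr false-positive rate(s) in \[0, 1\].
#' @return transformed value(s).
#' @export
fpr_transform <- function(fpr) {
  if (any(fpr < 0 | fpr > 1)) stop_invalid("`fpr` must be in [0, 1]")
  exp(-100 * fpr)
}

#' Proportion of shared edges between equally dense networks
#'
#' The number of edges present in both networks divided by the (common)
#' number of selected edges; 1 means identical edge sets.
#'
#' @param net_a,net_b `binary_network`s on the same node set with the same
#'   number of edges.
#' @return overlap proportion in \[0, 1\].
#' @export
edge_overlap <- function(net_a, net_b) {
  if (net_a$n_nodes != net_b$n_nodes)
    stop_invalid("networks have different node sets")
  ka <- nrow(net_a$edges)
  kb <- nrow(net_b$edges)
  if (ka != kb)
    stop_invalid("overlap requires matched densities (", ka, " vs ", kb,
                 " edges)")
  if (ka == 0L) return(1)
  sum(pair_keys(net_a$edges) %in% pair_keys(net_b$edges)) / ka
}

#' Within- and between-area connectivity across parcellation levels
#'
#' Checks whether a finer parcellation's network respects the structure of
#' a coarser one: `within` is the fraction of coarse areas that were split
#' into several fine ROIs and contain at least one fine edge internal to
#' the area; `between` is the fraction of area pairs connected in the
#' coarse network that are spanned by at least one fine edge.
#'
#' @param coarse_net `binary_network` on the coarse areas.
#' @param fine_net `binary_network` on the fine ROIs.
#' @param mapping integer vector, coarse area index of every fine ROI.
#' @return list with proportions `within` and `between` (`NA` when no area
#'   was split / the coarse network has no edges).
#' @export
area_connectivity <- function(coarse_net, fine_net, mapping) {
  if (length(mapping) != fine_net$n_nodes)
    stop_invalid("`mapping` must cover all fine nodes")
  if (any(mapping < 1L | mapping > coarse_net$n_nodes))
    stop_invalid("`mapping` refers to unknown coarse areas")
  fe <- fine_net$edges
  a1 <- if (nrow(fe) > 0L) mapping[fe[, 1L]] else integer(0)
  a2 <- if (nrow(fe) > 0L) mapping[fe[, 2L]] else integer(0)

  split_areas <- as.integer(names(which(table(mapping) > 1L)))
  within <- if (length(split_areas) == 0L) NA_real_ else {
    internally <- vapply(split_areas,
                         function(a) any(a1 == a & a2 == a), logical(1))
    mean(internally)
  }

  ce <- coarse_net$edges
  between <- if (nrow(ce) == 0L) NA_real_ else {
    fine_span <- unique(pair_keys(cbind(pmin(a1, a2), pmax(a1, a2))[
      a1 != a2, , drop = FALSE]))
    mean(pair_keys(ce) %in% fine_span)
  }
  list(within = within, between = between)
}

#' Full recovery report for one estimated network
#'
#' @inheritParams binned_tpr_fpr
#' @param weights optional `weight_matrix` for strength-based summaries.
#' @param reference_seeds seeds for small-worldness reference ensembles.
#' @return list of class `recovery_report` with overall and binned rates
#'   and metric discrepancies (absolute differences for global metrics,
#'   range-normalized summed differences for per-node metrics).
#' @export
recovery_report <- function(estimated, truth, bins = NULL, weights = NULL,
                            reference_seeds = 1:10) {
  rates <- tpr_fpr(estimated, truth)
  if (is.null(bins)) bins <- assign_degree_bins(
    truth, top_n = min(50L, max(1L, truth$n_nodes %/% 4L)))
  binned <- binned_tpr_fpr(estimated, truth, bins)
  m_est <- network_metrics(estimated, weights, reference_seeds)
  m_true <- network_metrics(truth, NULL, reference_seeds)
  globals <- c("avg_path_length", "global_clustering", "small_worldness",
               "n_components", "largest_component_size", "avg_betweenness")
  metric_abs_diff <- vapply(globals, function(nm) {
    a <- m_est[[nm]]; b <- m_true[[nm]]
    if (is.na(a) || is.na(b)) NA_real_ else abs(a - b)
  }, numeric(1))
  node_metrics <- c("degree", "strength", "betweenness")
  node_diff <- vapply(node_metrics, function(nm) {
    tv <- m_true[[nm]]
    if (max(tv) <= min(tv)) return(NA_real_)
    normalized_node_diff(m_est[[nm]], tv)
  }, numeric(1))
  structure(list(tpr = rates$tpr, fpr = rates$fpr,
                 tpr_by_binpair = binned$tpr_by_binpair,
                 fpr_by_binpair = binned$fpr_by_binpair,
                 metric_abs_diff = metric_abs_diff,
                 node_metric_normalized_diff = node_diff,
                 metrics_estimated = m_est, metrics_true = m_true),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> TPR = %.3f, FPR = %.5f\n", x$tpr, x$fpr))
  invisible(x)
}
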