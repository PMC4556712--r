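#' Average shortest-path length
#'
#' Mean geodesic distance over reachable ordered node pairs; pairs in
#' different components are excluded from the average (the convention of
#' the underlying graph library, which matters for fragmented estimated
#' networks).
#'
#' @param net a `binary_network`, `network_topology` or igraph graph.
#' @return average path length in steps; error if no pair is reachable.
#' @export
average_path_length <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0L)
    stop_invalid("no reachable pairs: graph has no edges")
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Global clustering, triangle count and local transitivity
#'
#' Global transitivity is 3 x triangles / connected triples; local
#' transitivity of a node is the fraction of its neighbor pairs that are
#' themselves connected (NaN for degree < 2, reported as `NA`).
#'
#' @inheritParams average_path_length
#' @return list with `global_clustering`, `n_triangles` and
#'   `local_transitivity` (per-node vector).
#' @export
clustering_and_triangles <- function(net) {
  g <- as_igraph(net)
  tri <- sum(igraph::count_triangles(g)) / 3
  glob <- igraph::transitivity(g, type = "global")
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  loc[is.nan(loc)] <- NA_real_
  list(global_clustering = if (is.nan(glob)) 0 else glob,
       n_triangles = as.integer(round(tri)),
       local_transitivity = loc)
}

#' Small-worldness index
#'
#' Humphries-Gurney index \eqn{(C/C_{rand}) / (L/L_{rand})}: clustering and
#' average path length relative to random networks of identical node and
#' edge count. The reference values are means over an ensemble of
#' Erdős–Rényi graphs generated from `reference_seeds` (default 10); a
#' closed-form reference (`reference = "analytic"`: \eqn{C_{rand} =
#' \bar{k}/(n-1)}, \eqn{L_{rand} = \ln n / \ln \bar{k}}) is available for
#' speed.
#'
#' @inheritParams average_path_length
#' @param reference_seeds integer seeds for the simulated reference
#'   ensemble.
#' @param reference `"simulated"` (default) or `"analytic"`.
#' @return the small-worldness index (about 1 for random graphs).
#' @export
small_worldness <- function(net, reference_seeds = 1:10,
                            reference = c("simulated", "analytic")) {
  reference <- match.arg(reference)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0L) stop_invalid("graph has no edges")
  C <- igraph::transitivity(g, type = "global")
  L <- igraph::mean_distance(g, directed = FALSE)
  if (reference == "analytic") {
    kbar <- 2 * m / n
    C_rand <- kbar / (n - 1)
    L_rand <- log(n) / log(kbar)
  } else {
    refs <- lapply(reference_seeds, function(s) {
      gr <- with_seed(s, igraph::sample_gnm(n, m))
      c(C = igraph::transitivity(gr, type = "global"),
        L = igraph::mean_distance(gr, directed = FALSE))
    })
    refs <- do.call(rbind, refs)
    C_rand <- mean(refs[, "C"])
    L_rand <- mean(refs[, "L"])
  }
  if (!is.finite(C_rand) || C_rand == 0)
    stop_invalid("degenerate reference: expected random clustering is 0")
  (C / C_rand) / (L / L_rand)
}

#' Connected components
#'
#' @inheritParams average_path_length
#' @return list with `n_components` (isolated nodes count as components)
#'   and `largest_size`.
#' @export
components_summary <- function(net) {
  comp <- igraph::components(as_igraph(net))
  list(n_components = as.integer(comp$no),
       largest_size = as.integer(if (comp$no > 0L) max(comp$csize) else 0L))
}

#' Betweenness centrality
#'
#' Unweighted shortest-path betweenness with fractional credit for tied
#' geodesics, computed on the binarized network.
#'
#' @inheritParams average_path_length
#' @return list with `per_node` vector and `average`.
#' @export
betweenness_centrality <- function(net) {
  b <- igraph::betweenness(as_igraph(net), directed = FALSE)
  list(per_node = as.numeric(b), average = mean(b))
}

#' Degree and (absolute-weight) strength
#'
#' Strength of a node is the sum of absolute weights over its selected
#' edges; absolute values are used because partial-correlation weights may
#' be negative.
#'
#' @param net a `binary_network` or `network_topology`.
#' @param weights optional `weight_matrix` (or plain matrix) supplying edge
#'   weights for the strength.
#' @return list with integer `degree` and numeric `strength` (equal to
#'   degree when `weights` is `NULL`, i.e. unit weights).
#' @export
degree_and_strength <- function(net, weights = NULL) {
  deg <- as.integer(igraph::degree(as_igraph(net)))
  if (is.null(weights)) return(list(degree = deg, strength = as.numeric(deg)))
  W <- if (inherits(weights, "weight_matrix")) weights$values else weights
  stopifnot(is.matrix(W), nrow(W) == net$n_nodes)
  s <- numeric(net$n_nodes)
  e <- net$edges
  if (nrow(e) > 0L) {
    w <- abs(W[cbind(e[, 1L], e[, 2L])])
    for (col in 1:2) {
      agg <- tapply(w, e[, col], sum)
      s[as.integer(names(agg))] <- s[as.integer(names(agg))] + agg
    }
  }
  list(degree = deg, strength = s)
}

#' Full metrics report for a network
#'
#' Bundles the network characteristics used by the benchmark into one
#' report.
#'
#' @inheritParams degree_and_strength
#' @param reference_seeds seeds for the small-worldness reference ensemble.
#' @return list of class `metrics_report`.
#' @export
network_metrics <- function(net, weights = NULL, reference_seeds = 1:10) {
  g <- as_igraph(net)
  clu <- clustering_and_triangles(net)
  comp <- components_summary(net)
  btw <- betweenness_centrality(net)
  ds <- degree_and_strength(net, weights)
  has_edges <- igraph::ecount(g) > 0L
  structure(list(
    avg_path_length = if (has_edges) average_path_length(net) else NA_real_,
    global_clustering = clu$global_clustering,
    n_triangles = clu$n_triangles,
    local_transitivity = clu$local_transitivity,
    small_worldness = if (has_edges && clu$global_clustering > 0)
      small_worldness(net, reference_seeds) else NA_real_,
    n_components = comp$n_components,
    largest_component_size = comp$largest_size,
    avg_betweenness = btw$average,
    betweenness = btw$per_node,
    degree = ds$degree,
    strength = ds$strength
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  scalars <- c("avg_path_length", "global_clustering", "n_triangles",
               "small_worldness", "n_components", "largest_component_size",
               "avg_betweenness")
  for (s in scalars) cat(sprintf("  %-24s %s\n", s, format(x[[s]])))
  cat(sprintf("  %-24s mean %.3g\n", "degree", mean(x$degree)))
  cat(sprintf("  %-24s mean %.3g\n", "strength", mean(x$strength)))
  invisible(x)
}
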