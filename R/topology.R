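#' Undirected simple graph used as ground truth
#'
#' A `network_topology` is a plain container for an undirected simple graph:
#' an integer node count and a set of unordered node pairs. Node indices are
#' 1-based (R convention) and contiguous. It is the ground-truth object that
#' Gaussian graphical models are built on and that estimated networks are
#' scored against.
#'
#' @param n_nodes integer, number of nodes (>= 1).
#' @param edges two-column matrix of node index pairs (any order; normalized
#'   to i < j, lexicographically sorted, duplicates dropped). `NULL` for an
#'   empty edge set.
#' @param labels optional character vector of node labels, length `n_nodes`.
#' @return An object of class `network_topology` with fields `n_nodes`,
#'   `edges` (k x 2 integer matrix) and `labels`.
#' @export
network_topology <- function(n_nodes, edges = NULL, labels = NULL) {
  if (!is_count(n_nodes, min = 1L))
    stop_invalid("`n_nodes` must be a positive integer")
  edges <- canonical_edges(edges)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop_invalid("edge endpoints out of range 1..n_nodes")
    if (any(edges[, 1L] == edges[, 2L]))
      stop_invalid("self-loops are not allowed")
  }
  if (!is.null(labels) && length(labels) != n_nodes)
    stop_invalid("`labels` must have length n_nodes")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 labels = labels),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d nodes, %d edges (density %.4g)\n",
              x$n_nodes, nrow(x$edges),
              if (x$n_nodes > 1L)
                nrow(x$edges) / (x$n_nodes * (x$n_nodes - 1) / 2) else 0))
  invisible(x)
}

#' Number of edges of a topology or binary network
#' @param x a `network_topology` or `binary_network`.
#' @return integer edge count.
#' @export
n_edges <- function(x) nrow(x$edges)

# --- igraph interop ---------------------------------------------------------

#' Convert to an igraph graph
#' @param x a `network_topology` or `binary_network`.
#' @return an undirected simple `igraph` graph with the same node count.
#' @export
as_igraph <- function(x) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.network_topology <- function(x) {
  g <- igraph::make_empty_graph(n = x$n_nodes, directed = FALSE)
  if (nrow(x$edges) > 0L) g <- igraph::add_edges(g, t(x$edges))
  g
}

#' @export
as_igraph.binary_network <- as_igraph.network_topology

#' @export
as_igraph.igraph <- function(x) x

from_igraph <- function(g) {
  network_topology(igraph::vcount(g),
                   igraph::as_edgelist(g, names = FALSE))
}

# --- generators -------------------------------------------------------------

#' Erdős–Rényi random topology
#'
#' Generates a uniform random graph, either with a fixed per-edge presence
#' probability (G(n, p)) or with an exact number of edges sampled uniformly
#' without replacement (G(n, m)). The benchmark's "random network" rows use
#' the exact-count form so that printed edge counts are reproduced exactly.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param probability per-edge presence probability in \[0, 1\]. Exactly one
#'   of `probability` and `count` must be given.
#' @param count exact number of edges, at most `n_nodes * (n_nodes - 1) / 2`.
#' @param seed integer RNG seed; the same seed yields an identical graph.
#' @return a `network_topology`.
#' @export
generate_random <- function(n_nodes, probability = NULL, count = NULL,
                            seed = 1L) {
  if (!is_count(n_nodes, min = 2L))
    stop_invalid("`n_nodes` must be an integer >= 2")
  if (is.null(probability) == is.null(count))
    stop_invalid("give exactly one of `probability` or `count`")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  g <- if (!is.null(count)) {
    if (!is_count(count) || count > max_edges)
      stop_invalid("`count` must be an integer in [0, n(n-1)/2]")
    with_seed(seed, igraph::sample_gnm(n_nodes, count))
  } else {
    if (!is.numeric(probability) || probability < 0 || probability > 1)
      stop_invalid("`probability` must be in [0, 1]")
    with_seed(seed, igraph::sample_gnp(n_nodes, probability))
  }
  from_igraph(g)
}

#' Acquaintance-model small-world topology
#'
#' Iterative "introduce two of my acquaintances" growth model from social
#' network theory. Each iteration a uniformly chosen node introduces two of
#' its neighbors to each other (nodes with fewer than two neighbors instead
#' link to a random other node); with probability `p_d` a uniformly chosen
#' node then "dies": its edges are removed and it is replaced by a newcomer
#' with a single random link. Low `p_d` yields small-world graphs with hubs;
#' higher `p_d` suppresses hub formation. The published description of the
#' model leaves the initial state open; this implementation starts from an
#' Erdős–Rényi seed graph with mean degree 2 (a reconstruction, documented
#' in the methods vignette).
#'
#' @param n_nodes number of nodes.
#' @param p_d per-iteration node-replacement probability in \[0, 1\].
#' @param iterations number of update steps (>= 0); 0 returns the seed graph.
#' @param seed integer RNG seed.
#' @return a `network_topology`.
#' @export
generate_acquaintance <- function(n_nodes, p_d, iterations, seed = 1L) {
  if (!is_count(n_nodes, min = 2L))
    stop_invalid("`n_nodes` must be an integer >= 2")
  if (!is.numeric(p_d) || p_d < 0 || p_d > 1)
    stop_invalid("`p_d` must be in [0, 1]")
  if (!is_count(iterations))
    stop_invalid("`iterations` must be a non-negative integer")
  init <- generate_random(n_nodes, probability = 2 / (n_nodes - 1),
                          seed = seed)
  el <- with_seed(seed + 1L, {
    acquaintance_run(n_nodes, init$edges - 1L, p_d, as.double(iterations))
  })
  network_topology(n_nodes, el + 1L)
}

#' Preferential-attachment (scale-free) topology
#'
#' Linear preferential attachment: nodes are added one at a time, each
#' bringing `m` edges attached to existing nodes with probability
#' proportional to their current degree. Multi-edges and self-loops that the
#' growth process can produce are removed afterwards (simplification), so
#' the final edge count can be slightly below `m * (n_nodes - 1)`.
#'
#' @param n_nodes number of nodes; must exceed `m`.
#' @param m edges added per time step (>= 1).
#' @param seed integer RNG seed.
#' @return a `network_topology` with a heavy-tailed degree distribution.
#' @export
generate_preferential <- function(n_nodes, m, seed = 1L) {
  if (!is_count(m, min = 1L)) stop_invalid("`m` must be an integer >= 1")
  if (!is_count(n_nodes, min = 2L) || n_nodes <= m)
    stop_invalid("`n_nodes` must exceed `m`")
  g <- with_seed(seed, {
    igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE,
                      algorithm = "psumtree-multiple")
  })
  from_igraph(igraph::simplify(g))
}

#' Restrict a topology to its largest connected component
#'
#' Drops all nodes outside the largest connected component (isolated nodes
#' in particular) and compacts node indices to 1..n'. Ground-truth networks
#' are required to consist of a single component.
#'
#' @param topology a `network_topology`.
#' @return a `network_topology` with exactly one connected component. The
#'   integer vector of retained original node indices is attached as
#'   attribute `"kept"`.
#' @export
finalize_connected <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  if (topology$n_nodes < 1L) stop_invalid("empty graph")
  g <- as_igraph(topology)
  comp <- igraph::components(g)
  if (comp$no == 0L) stop_invalid("empty graph")
  keep_id <- which.max(comp$csize)  # ties: first, i.e. lowest component id
  kept <- which(comp$membership == keep_id)
  remap <- integer(topology$n_nodes)
  remap[kept] <- seq_along(kept)
  edges <- topology$edges
  sel <- edges[, 1L] %in% kept & edges[, 2L] %in% kept
  out <- network_topology(length(kept),
                          cbind(remap[edges[sel, 1L]], remap[edges[sel, 2L]]),
                          labels = topology$labels[kept])
  attr(out, "kept") <- kept
  out
}

# --- candidate selection ----------------------------------------------------

#' Summary metrics of a topology used for representative selection
#'
#' @param topology a `network_topology`.
#' @param reference_seeds seeds for the random reference ensemble of the
#'   small-worldness index (see [small_worldness()]).
#' @return named numeric vector: transitivity, average path length, average
#'   degree, degree variance, average betweenness, small-worldness.
#' @export
topology_metrics <- function(topology, reference_seeds = 1:10) {
  g <- as_igraph(topology)
  deg <- igraph::degree(g)
  c(transitivity = igraph::transitivity(g, type = "global"),
    avg_path_length = igraph::mean_distance(g, directed = FALSE),
    avg_degree = mean(deg),
    degree_variance = var(deg),
    avg_betweenness = mean(igraph::betweenness(g, directed = FALSE)),
    small_worldness = small_worldness(topology, reference_seeds))
}

#' Pick the most representative candidate network
#'
#' Given per-candidate metric vectors, each metric is z-scored across
#' candidates (so metrics with different units weigh equally) and the
#' candidate with the smallest Euclidean distance from the group mean (the
#' zero vector after z-scoring) is returned. Ties break to the lowest index.
#' A metric that is constant across candidates contributes zero to every
#' distance.
#'
#' @param candidates list of equal-length numeric metric vectors, or a
#'   matrix with one row per candidate.
#' @return integer index of the selected candidate.
#' @export
select_representative <- function(candidates) {
  m <- if (is.matrix(candidates)) candidates else do.call(rbind, candidates)
  if (is.null(m) || nrow(m) == 0L) stop_invalid("no candidates")
  if (nrow(m) == 1L) return(1L)
  z <- apply(m, 2L, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col))
    else (col - mean(col)) / s
  })
  d2 <- rowSums(as.matrix(z)^2)
  which.min(d2)  # which.min is tie-broken to the first (lowest) index
}
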