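#' Binary network from the k strongest weights
#'
#' Keeps exactly the `k` off-diagonal weights with the largest absolute
#' value. Fixed-density selection makes method comparisons depend only on
#' the estimator, not on a thresholding rule. Ties are broken
#' deterministically: larger signed weight first, then lexicographic node
#' pair.
#'
#' @param weights a `weight_matrix` or plain symmetric p x p matrix.
#' @param k number of edges to keep, in \[0, p(p-1)/2\].
#' @return a `binary_network`: fields `n_nodes`, `edges`, `source_method`,
#'   `k_selected`.
#' @export
select_top_k <- function(weights, k) {
  W <- if (inherits(weights, "weight_matrix")) weights$values else weights
  method <- if (inherits(weights, "weight_matrix")) weights$method else NA
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  p <- nrow(W)
  max_e <- p * (p - 1) / 2
  if (!is_count(k) || k > max_e)
    stop_invalid("`k` must be an integer in [0, p(p-1)/2]")
  ut <- which(upper.tri(W))
  w <- W[ut]
  i <- row(W)[ut]
  j <- col(W)[ut]
  ord <- order(-abs(w), -w, i, j)
  keep <- ord[seq_len(k)]
  binary_network(p, cbind(i[keep], j[keep]), source_method = method,
                 k_selected = k)
}

#' Construct a binary network
#'
#' @param n_nodes node count.
#' @param edges two-column matrix of selected node pairs.
#' @param source_method estimator tag the network came from (or `NA`).
#' @param k_selected number of selected edges (defaults to `nrow(edges)`).
#' @return object of class `binary_network`.
#' @export
binary_network <- function(n_nodes, edges = NULL, source_method = NA,
                           k_selected = NULL) {
  edges <- canonical_edges(edges)
  if (is.null(k_selected)) k_selected <- nrow(edges)
  if (nrow(edges) != k_selected)
    stop_invalid("edge set size does not match k_selected ",
                 "(duplicate or missing pairs?)")
  if (nrow(edges) > 0L && (any(edges < 1L) || any(edges > n_nodes)))
    stop_invalid("edge endpoints out of range")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 source_method = source_method,
                 k_selected = as.integer(k_selected)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d selected edges (method: %s)\n",
              x$n_nodes, x$k_selected, x$source_method))
  invisible(x)
}

#' Edge counts for the three density criteria
#'
#' The benchmark evaluates each estimator at the true density and at 20%
#' too few / too many edges. Rounds half away from zero.
#'
#' @param true_edge_count number of edges of the generating network (>= 0).
#' @return named integer vector `(k_minus, k_true, k_plus)` =
#'   `(round(0.8 E), E, round(1.2 E))`.
#' @export
density_variants <- function(true_edge_count) {
  if (!is_count(true_edge_count))
    stop_invalid("`true_edge_count` must be a non-negative integer")
  c(k_minus = as.integer(round_half_up(0.8 * true_edge_count)),
    k_true = as.integer(true_edge_count),
    k_plus = as.integer(round_half_up(1.2 * true_edge_count)))
}

#' Edge count of a fixed-density rule
#'
#' Number of edges retained when selecting a fixed proportion of all
#' possible edges, e.g. the 3% rule used for parcellated data
#' (`floor(prop * p(p-1)/2)`).
#'
#' @param n_nodes node count.
#' @param proportion density in \[0, 1\] (default 0.03).
#' @return integer edge count.
#' @export
fixed_density_k <- function(n_nodes, proportion = 0.03) {
  if (!is_count(n_nodes, min = 2L)) stop_invalid("`n_nodes` must be >= 2")
  if (proportion < 0 || proportion > 1)
    stop_invalid("`proportion` must be in [0, 1]")
  as.integer(floor(proportion * n_nodes * (n_nodes - 1) / 2))
}
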