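#' @useDynLib ggmbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov rnorm runif sd var
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round() uses round-half-even; edge-count arithmetic wants half away from zero
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# canonical string keys for unordered node pairs, rows of a k x 2 matrix
pair_keys <- function(edges) {
  if (length(edges) == 0L) return(character(0))
  paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]),
        sep = "-")
}

# normalize an edge matrix: integer, i < j per row, sorted lexicographically,
# duplicates dropped
canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
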