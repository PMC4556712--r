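#' Write / read an edge list as TSV
#'
#' One line per edge, columns `node_i`, `node_j` with i < j, 1-based
#' indices. Header comment lines (starting with `#`) record the node count
#' and, for binary networks, the source method and k.
#'
#' @param x a `network_topology` or `binary_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d", x$n_nodes), con)
  if (inherits(x, "binary_network"))
    writeLines(sprintf("# method=%s k=%d", x$source_method, x$k_selected),
               con)
  writeLines("node_i\tnode_j", con)
  if (nrow(x$edges) > 0L)
    writeLines(paste(x$edges[, 1L], x$edges[, 2L], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @param path file written by [write_edge_list()].
#' @return a `network_topology`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  n_nodes <- as.integer(sub(".*n_nodes=(\\d+).*", "\\1",
                            grep("n_nodes=", hdr, value = TRUE)[1L]))
  body <- lines[!grepl("^#", lines)][-1L]  # drop column header
  edges <- if (length(body) == 0L) NULL else {
    do.call(rbind, lapply(strsplit(body, "\t"), as.integer))
  }
  network_topology(n_nodes, edges)
}

#' Write a topology as sparse Matrix Market adjacency
#'
#' @param topology a `network_topology` or `binary_network`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_adjacency_mtx <- function(topology, path) {
  p <- topology$n_nodes
  e <- topology$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                            j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(p, p))
  Matrix::writeMM(A, path)
  invisible(path)
}

#' Write / read a dense numeric matrix as CSV
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a time series matrix as TSV (rows = nodes)
#'
#' @param ts a `time_series_matrix`.
#' @param path file path.
#' @param labels optional node labels used as row names.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path, labels = NULL) {
  x <- ts_values(ts)
  df <- data.frame(node = if (is.null(labels)) paste0("n", seq_len(nrow(x)))
                   else labels, x, check.names = FALSE)
  names(df) <- c("node", paste0("t", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @export
read_time_series <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, class = c("time_series_matrix", "matrix", "array"))
}

#' Write a ranked edge list of an estimated weight matrix
#'
#' TSV with columns node_i, node_j, weight and the rank of |weight|
#' (1 = strongest).
#'
#' @param weights a `weight_matrix`.
#' @param path file path.
#' @param top optional: write only the strongest `top` pairs.
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(weights, path, top = NULL) {
  W <- weights$values
  ut <- which(upper.tri(W))
  i <- row(W)[ut]; j <- col(W)[ut]; w <- W[ut]
  ord <- order(-abs(w), -w, i, j)
  if (!is.null(top)) ord <- ord[seq_len(min(top, length(ord)))]
  df <- data.frame(node_i = i[ord], node_j = j[ord], weight = w[ord],
                   rank = seq_along(ord))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a report (metrics / recovery / tuning) as JSON
#'
#' @param x a list-like report; matrices are written as nested arrays.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
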