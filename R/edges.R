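#' Vectorize the upper triangle of a symmetric matrix
#'
#' Connectivity matrices are stored between stages as edge vectors over the
#' upper triangle in row-major order: (1,2), (1,3), ..., (1,n), (2,3), ...,
#' (n-1,n). This ordering is the package-wide convention for clustering,
#' centroid correlation and edge tables.
#'
#' @param m symmetric numeric matrix.
#' @return numeric vector of length `n*(n-1)/2`.
#' @seealso [edges_to_mat()], [edge_labels()]
#' @export
mat_to_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  # t(m)[lower.tri(m)] walks the upper triangle of m row by row
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [mat_to_edges()]; the diagonal is set to `diag_value`.
#'
#' @param v edge vector in the package's row-major upper-triangle order.
#' @param n number of nodes.
#' @param diag_value value placed on the diagonal (default 0).
#' @return an `n x n` symmetric matrix.
#' @export
edges_to_mat <- function(v, n, diag_value = 0) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

#' Edge labels for the canonical upper-triangle ordering
#'
#' @param component_ids character vector of node labels.
#' @return character vector like `"C1_C2", "C1_C3", ...` matching
#'   [mat_to_edges()] ordering.
#' @export
edge_labels <- function(component_ids) {
  n <- length(component_ids)
  idx <- edge_index_pairs(n)
  paste(component_ids[idx[, 1]], component_ids[idx[, 2]], sep = "_")
}

# (i, j) node pairs, i < j, in row-major upper-triangle order
edge_index_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i = i, j = j)
}
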