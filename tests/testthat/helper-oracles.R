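# Independent brute-force oracles used to cross-check the implementation.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  D <- fw_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

oracle_nodal_efficiency <- function(A) {
  D <- fw_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (nrow(A) - 1)
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) return(0)
    tri <- sum(A[nb, nb]) / 2
    tri / (d * (d - 1) / 2)
  }, 0)
  mean(ci)
}

oracle_path_length <- function(A) {
  D <- fw_distances(A)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (length(d) == 0) NA_real_ else mean(d)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

oracle_modularity <- function(W, membership) {
  # direct double sum over node pairs: Q = 1/(2m) sum_ij (w_ij - k_i k_j / 2m) d(c_i, c_j)
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (membership[i] == membership[j])
        q <- q + W[i, j] - k[i] * k[j] / two_m
  q / two_m
}

# direct O(w*K) discrete convolution of a rectangle with a unit-area Gaussian,
# truncated to the central window
oracle_taper <- function(window_len, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- (-half):half
  g <- exp(-k^2 / (2 * sigma^2))
  g <- g / sum(g)
  rect <- rep(1, window_len)
  full_len <- window_len + 2 * half
  full <- numeric(full_len)
  for (i in seq_len(full_len))
    for (j in seq_len(window_len)) {
      ki <- i - j + 1  # index into g for offset (i - j)
      if (ki >= 1 && ki <= length(g)) full[i] <- full[i] + rect[j] * g[ki]
    }
  full[(half + 1):(half + window_len)]
}

random_binary_graph <- function(n, p_edge = NULL) {
  if (is.null(p_edge)) p_edge <- runif(1, 0.15, 0.8)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < p_edge)
  A <- A + t(A)
  A
}

as_binary_graph <- function(A) {
  structure(list(adjacency = A, n_nodes = nrow(A), n_edges = sum(A) / 2,
                 flagged = FALSE), class = "binary_graph")
}

# small deterministic window_series built from explicit matrices
fake_window_series <- function(mats, subject_id = "sub-001",
                               component_ids = NULL) {
  n <- nrow(mats[[1]])
  if (is.null(component_ids)) component_ids <- sprintf("C%d", seq_len(n))
  structure(list(subject_id = subject_id, z_matrices = mats,
                 window_starts = seq_along(mats) - 1L,
                 component_ids = component_ids,
                 params = list(window_len = NA, step = 1, taper_sigma = NA,
                               lasso_penalty = NA)),
            class = "window_series")
}
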