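#' Prepare a state centroid matrix for modularity analysis
#'
#' Community detection operates on a weighted, nonnegative, zero-diagonal
#' graph. Negative Fisher-z values are by default set to zero
#' (`negative = "zero"`); `negative = "abs"` uses absolute values instead.
#'
#' @param centroid_matrix symmetric matrix (e.g. [edges_to_mat()] of a state
#'   centroid).
#' @param negative `"zero"` or `"abs"`.
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
centroid_graph <- function(centroid_matrix, negative = c("zero", "abs")) {
  negative <- match.arg(negative)
  W <- as.matrix(centroid_matrix)
  stopifnot(nrow(W) == ncol(W), max(abs(W - t(W))) < 1e-8)
  W <- if (negative == "zero") pmax(W, 0) else abs(W)
  diag(W) <- 0
  W
}

#' Newman-Girvan weighted modularity Q
#'
#' `Q = sum_m (e_mm - a_m^2)` where `e_mm` is the fraction of total edge
#' weight inside module m and `a_m` the fraction of weight incident to m.
#' Q of the single-module partition is 0, and Q is invariant to uniform
#' rescaling of the weights.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal, positive total
#'   weight.
#' @param membership integer module id per node.
#' @return modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(weights, membership) {
  W <- as.matrix(weights)
  stopifnot(nrow(W) == ncol(W), all(W >= 0), all(diag(W) == 0),
            max(abs(W - t(W))) < 1e-8, length(membership) == nrow(W))
  total <- sum(W)
  if (total <= 0) stop("zero total weight")
  mods <- unique(membership)
  q <- 0
  for (m in mods) {
    sel <- membership == m
    e_mm <- sum(W[sel, sel]) / total
    a_m <- sum(W[sel, ]) / total
    q <- q + e_mm - a_m^2
  }
  q
}

as_partition <- function(membership, weights, seed) {
  membership <- as.integer(factor(membership, levels = unique(membership)))
  structure(list(module_of = membership,
                 q_value = modularity_q(weights, membership),
                 n_modules = length(unique(membership)),
                 seed = seed),
            class = "partition")
}

#' Louvain community detection
#'
#' Greedy two-phase Louvain algorithm (local moving plus aggregation) on a
#' weighted graph; node visit order depends on the seed. The returned Q is
#' recomputed with [modularity_q()] on the returned partition. If the best
#' partition found scores below the trivial single-module partition (Q = 0),
#' the single-module partition is returned.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal.
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed.
#' @return object of class `partition`: `module_of`, `q_value`, `n_modules`,
#'   `seed`.
#' @export
louvain_partition <- function(weights, resolution = 1, seed = 1L) {
  W <- as.matrix(weights)
  stopifnot(all(W >= 0), all(diag(W) == 0), max(abs(W - t(W))) < 1e-8)
  if (sum(W) <= 0) stop("zero total weight")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- withr::with_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  part <- as_partition(as.integer(memb), W, seed)
  if (part$q_value < 0) part <- as_partition(rep(1L, nrow(W)), W, seed)
  part
}

#' Consensus Louvain partition
#'
#' Runs Louvain `n_runs` times with distinct seeds, builds the node-by-node
#' co-assignment frequency matrix, zeroes entries below `tau`, and re-clusters
#' the consensus matrix; this repeats until all runs agree (the co-assignment
#' matrix is binary) or `max_rounds` rounds, resolving the stochasticity of
#' single Louvain runs.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal.
#' @param n_runs Louvain runs per round (default 100).
#' @param tau consensus threshold in (0, 1) (default 0.5).
#' @param seed master seed; run seeds are derived from it.
#' @param max_rounds round cap (default 50).
#' @return a `partition` for the original weights, with attribute
#'   `"converged"` (FALSE with a warning when the round cap is hit).
#' @export
consensus_partition <- function(weights, n_runs = 100, tau = 0.5, seed = 1L,
                                max_rounds = 50) {
  stopifnot(n_runs >= 2, tau > 0, tau < 1)
  W0 <- as.matrix(weights)
  W <- W0
  n <- nrow(W)
  converged <- FALSE
  membs <- NULL
  for (round in seq_len(max_rounds)) {
    membs <- lapply(seq_len(n_runs), function(r)
      louvain_partition(W, seed = seed + (round - 1) * n_runs + r)$module_of)
    Cf <- matrix(0, n, n)
    for (m in membs) Cf <- Cf + outer(m, m, "==")
    Cf <- Cf / n_runs
    diag(Cf) <- 0
    if (all(Cf %in% c(0, 1))) { converged <- TRUE; break }
    Cf[Cf < tau] <- 0
    if (sum(Cf) == 0) break  # nothing co-assigns: accept the current runs
    W <- Cf
  }
  if (!converged)
    warning("consensus clustering did not converge; returning current partition")
  part <- as_partition(membs[[1]], W0, seed)
  attr(part, "converged") <- converged
  part
}

#' Modularity of each connectivity state centroid
#'
#' Convenience wrapper: rebuilds each state's centroid matrix, prepares the
#' nonnegative graph and runs [consensus_partition()], reporting Q per state.
#'
#' @param model a fitted `state_model`.
#' @param n_components number of components (nodes).
#' @param negative negative-weight handling, see [centroid_graph()].
#' @param n_runs,tau,seed consensus parameters.
#' @return named list of `partition` objects, one per state.
#' @export
state_modularity <- function(model, n_components, negative = "zero",
                             n_runs = 100, tau = 0.5, seed = 1L) {
  stopifnot(inherits(model, "state_model"))
  out <- lapply(seq_len(model$k), function(m) {
    W <- centroid_graph(edges_to_mat(model$centroids[m, ], n_components),
                        negative = negative)
    consensus_partition(W, n_runs = n_runs, tau = tau, seed = seed + m)
  })
  stats::setNames(out, rownames(model$centroids))
}
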