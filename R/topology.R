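#' Sparsity grid of binarization thresholds
#'
#' @param from,to,by grid limits and spacing (defaults 0.10, 0.35, 0.01).
#' @return object of class `threshold_profile` (strictly increasing
#'   sparsities in (0, 1)).
#' @export
threshold_profile <- function(from = 0.10, to = 0.35, by = 0.01) {
  s <- seq(from, to, by = by)
  stopifnot(all(s > 0), all(s < 1), all(diff(s) > 0))
  structure(list(sparsities = s), class = "threshold_profile")
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `round(sparsity * n(n-1)/2)` largest strictly positive edges
#' (round-half-up; ties broken by the lexicographic row-major edge index) and
#' discards the rest; only positive connectivity values are eligible. If the
#' matrix holds fewer positive edges than the target, all positive edges are
#' kept and the graph is flagged.
#'
#' @param z_matrix symmetric connectivity matrix.
#' @param sparsity target edge fraction in (0, 1).
#' @return object of class `binary_graph`: `adjacency` (0/1, zero diagonal),
#'   `n_nodes`, `n_edges`, `flagged`.
#' @export
binarize_at_sparsity <- function(z_matrix, sparsity) {
  stopifnot(sparsity > 0, sparsity < 1)
  n <- nrow(z_matrix)
  v <- mat_to_edges(z_matrix)
  max_edges <- length(v)
  target <- floor(sparsity * max_edges + 0.5)  # round half up
  pos <- which(v > 0)
  flagged <- length(pos) < target
  keep_n <- min(target, length(pos))
  keep <- if (keep_n > 0) pos[order(-v[pos], pos)][seq_len(keep_n)] else integer(0)
  vb <- numeric(max_edges)
  vb[keep] <- 1
  A <- edges_to_mat(vb, n)
  structure(list(adjacency = A, n_nodes = n, n_edges = keep_n,
                 flagged = flagged), class = "binary_graph")
}

graph_from_binary <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' `1/Inf = 0` for disconnected pairs; in \[0, 1\], equal to 1 for a complete
#' graph.
#'
#' @param g a [binarize_at_sparsity()] result.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n_nodes >= 2)
  mean(nodal_efficiency(g))
}

#' Nodal efficiency
#'
#' For node i, the mean over all other nodes j of `1/d(i, j)`.
#'
#' @inheritParams global_efficiency
#' @return length-`n_nodes` vector.
#' @export
nodal_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n_nodes >= 2)
  D <- igraph::distances(graph_from_binary(g))
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (g$n_nodes - 1)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (0 for nodes of degree < 2).
#'
#' @inheritParams global_efficiency
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  A <- g$adjacency
  vals <- vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- structure(list(adjacency = A[nb, nb, drop = FALSE],
                          n_nodes = length(nb)), class = "binary_graph")
    global_efficiency(sub)
  }, 0)
  mean(vals)
}

#' Mean clustering coefficient
#'
#' Average of the nodal clustering coefficients (triangles around a node over
#' possible triangles); nodes with degree < 2 contribute 0.
#'
#' @inheritParams global_efficiency
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n_nodes >= 3)
  ci <- igraph::transitivity(graph_from_binary(g), type = "localundirected",
                             isolates = "zero")
  ci[is.na(ci)] <- 0
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered node pairs at finite
#' distance; `NA` (undefined) when no finite pair exists (empty graph).
#'
#' @inheritParams global_efficiency
#' @return scalar, or `NA` when undefined.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n_nodes >= 2)
  D <- igraph::distances(graph_from_binary(g))
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

# one Maslov-Sneppen degree-preserving rewire; complete/empty graphs are
# returned unchanged (no swap is possible)
rewire_preserving_degree <- function(g, n_swaps) {
  ig <- graph_from_binary(g)
  ne <- igraph::ecount(ig)
  if (ne == 0 || ne == g$n_nodes * (g$n_nodes - 1) / 2) return(g)
  rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_swaps))
  A <- as.matrix(igraph::as_adjacency_matrix(rw, sparse = FALSE))
  structure(list(adjacency = A, n_nodes = g$n_nodes, n_edges = ne,
                 flagged = g$flagged), class = "binary_graph")
}

#' Small-world metrics against degree-preserving random references
#'
#' Generates `n_random` Maslov-Sneppen rewired graphs (10 x edge-count
#' attempted swaps each) and returns `gamma = C / <C_rand>`,
#' `lambda = L / <L_rand>` and `sigma = gamma / lambda`. Complete or empty
#' graphs cannot be rewired, so their reference equals the input and all
#' three metrics are 1. `NA` when `<C_rand>` is 0 or L is undefined.
#'
#' @param g a `binary_graph` with at least one edge.
#' @param n_random number of random reference graphs (default 100).
#' @param seed integer seed.
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
small_world_metrics <- function(g, n_random = 100, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"), sum(g$adjacency) > 0)
  C <- clustering_coefficient(g)
  L <- characteristic_path_length(g)
  refs <- withr::with_seed(seed, {
    lapply(seq_len(n_random), function(i)
      rewire_preserving_degree(g, n_swaps = 10 * g$n_edges))
  })
  C_rand <- mean(vapply(refs, clustering_coefficient, 0))
  L_rand <- mean(vapply(refs, characteristic_path_length, 0))
  if (is.na(L) || is.na(L_rand) || C_rand == 0 || L_rand == 0)
    return(list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_))
  gamma <- C / C_rand
  lambda <- L / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Area under the curve over sparsity thresholds
#'
#' Trapezoidal integral of a per-threshold metric over the sparsity axis,
#' removing the dependence on any single threshold. Isolated undefined values
#' are linearly interpolated from defined neighbours; an all-undefined series
#' yields `NA`.
#'
#' @param values one metric value per threshold.
#' @param profile a [threshold_profile()].
#' @return scalar AUC.
#' @export
auc_over_thresholds <- function(values, profile) {
  stopifnot(inherits(profile, "threshold_profile"))
  s <- profile$sparsities
  if (length(values) != length(s)) stop("one value per threshold required")
  if (all(is.na(values))) return(NA_real_)
  if (any(is.na(values))) {
    ok <- !is.na(values)
    values <- if (sum(ok) == 1) rep(values[ok], length(s)) else
      stats::approx(s[ok], values[ok], xout = s, rule = 2)$y
  }
  sum(diff(s) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Coefficient of variation of a per-window series
#'
#' Default definition `sd_over_mean`: sample SD (denominator W-1) divided by
#' the mean (`NA` when the mean is 0); a constant series gives 0. The
#' reciprocal `mean_over_sd` definition is also available (`NA` for a
#' zero-variance series).
#'
#' @param series numeric vector, length >= 2.
#' @param definition `"sd_over_mean"` (default) or `"mean_over_sd"`.
#' @return scalar CV, `NA` when undefined.
#' @export
cv_over_windows <- function(series, definition = c("sd_over_mean", "mean_over_sd")) {
  definition <- match.arg(definition)
  series <- series[!is.na(series)]
  if (length(series) < 2) return(NA_real_)
  m <- mean(series)
  s <- stats::sd(series)
  if (definition == "sd_over_mean") {
    if (s == 0) return(0)          # constant series: no variability
    if (m == 0) return(NA_real_)   # varying around zero mean: undefined
    s / m
  } else {
    if (s == 0) return(NA_real_)
    m / s
  }
}

#' Dynamic topology profile of a window series
#'
#' For every window and sparsity threshold the z-matrix is binarized and the
#' global metrics (E_g, E_loc, C, L, gamma, lambda, sigma) plus nodal
#' efficiency are computed; each metric is then reduced to a per-window AUC
#' over the threshold grid, and finally to a coefficient of variation across
#' windows (per global metric and per node).
#'
#' @param series a [windowed_fc()] result.
#' @param profile a [threshold_profile()].
#' @param n_random random reference graphs per window/threshold for the
#'   small-world metrics (default 100).
#' @param seed integer seed.
#' @param cv_definition forwarded to [cv_over_windows()].
#' @return object of class `topology_profile`: `auc` (windows x 7 global
#'   metrics), `nodal_auc` (windows x nodes), `cv` (per global metric),
#'   `nodal_cv` (per node), `flagged_windows`.
#' @export
dynamic_topology <- function(series, profile = threshold_profile(),
                             n_random = 100, seed = 1L,
                             cv_definition = "sd_over_mean") {
  stopifnot(inherits(series, "window_series"))
  metrics <- c("E_g", "E_loc", "C", "L", "gamma", "lambda", "sigma")
  W <- length(series$z_matrices)
  n_nodes <- nrow(series$z_matrices[[1]])
  n_thr <- length(profile$sparsities)
  auc <- matrix(NA_real_, W, length(metrics), dimnames = list(NULL, metrics))
  nodal_auc <- matrix(NA_real_, W, n_nodes)
  flagged <- logical(W)
  for (wi in seq_len(W)) {
    vals <- matrix(NA_real_, n_thr, length(metrics),
                   dimnames = list(NULL, metrics))
    nodal_vals <- matrix(NA_real_, n_thr, n_nodes)
    for (ti in seq_len(n_thr)) {
      g <- binarize_at_sparsity(series$z_matrices[[wi]], profile$sparsities[ti])
      flagged[wi] <- flagged[wi] || g$flagged
      if (g$n_edges == 0) next
      ne <- nodal_efficiency(g)
      nodal_vals[ti, ] <- ne
      sw <- small_world_metrics(g, n_random = n_random,
                                seed = seed + wi * 1000 + ti)
      vals[ti, ] <- c(mean(ne), local_efficiency(g), clustering_coefficient(g),
                      characteristic_path_length(g),
                      sw$gamma, sw$lambda, sw$sigma)
    }
    auc[wi, ] <- apply(vals, 2, auc_over_thresholds, profile = profile)
    nodal_auc[wi, ] <- apply(nodal_vals, 2, auc_over_thresholds, profile = profile)
  }
  structure(list(
    subject_id = series$subject_id,
    auc = auc,
    nodal_auc = nodal_auc,
    cv = apply(auc, 2, cv_over_windows, definition = cv_definition),
    nodal_cv = apply(nodal_auc, 2, cv_over_windows, definition = cv_definition),
    flagged_windows = which(flagged)
  ), class = "topology_profile")
}
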