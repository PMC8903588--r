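# L1 distances from every row of X to every centroid row of C -> n x k matrix
l1_dist_to_centroids <- function(X, C) {
  k <- nrow(C)
  D <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    D[, j] <- rowSums(abs(sweep(X, 2, C[j, ], check.margin = FALSE)))
  D
}

colMedians <- function(X) apply(X, 2, stats::median)

kmedians_once <- function(X, k, max_iter) {
  n <- nrow(X)
  C <- X[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    D <- l1_dist_to_centroids(X, C)
    assign <- max.col(-D, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    for (j in which(tabulate(assign, k) == 0)) {
      far <- which.max(D[cbind(seq_len(n), assign)])
      C[j, ] <- X[far, ]
      assign[far] <- j
    }
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (j in seq_len(k))
      C[j, ] <- colMedians(X[assign == j, , drop = FALSE])
  }
  D <- l1_dist_to_centroids(X, C)
  assign <- max.col(-D, ties.method = "first")
  list(centroids = C, labels = assign,
       cost = sum(D[cbind(seq_len(n), assign)]))
}

#' Cluster pooled windows into recurring connectivity states
#'
#' k-medians under the L1 (Manhattan) distance: windows are assigned to the
#' nearest centroid by L1 distance and each centroid is updated to the
#' component-wise median of its windows, so fitted centroids are the medians
#' of the matrices allocated to each state. The best of `n_init` random
#' initialisations by total L1 cost is kept, and states are relabelled by
#' descending total occurrence (state 1 = most windows).
#'
#' @param X pooled windows x edges matrix (see [pool_windows()]).
#' @param k number of states (>= 1).
#' @param n_init random restarts (default 100).
#' @param seed integer seed.
#' @param subject optional subject id per row; adds per-subject label
#'   sequences to the model.
#' @param max_iter iteration cap per restart (default 1000).
#' @return object of class `state_model`: `k`, `centroids` (k x edges),
#'   `labels`, `labels_by_subject` (when `subject` given), `total_cost`,
#'   `seed`.
#' @export
cluster_windows <- function(X, k, n_init = 100, seed = 1L, subject = NULL,
                            max_iter = 1000) {
  X <- as.matrix(X)
  stopifnot(k >= 1, nrow(X) >= k)
  if (nrow(unique(X)) < k) stop("k exceeds the number of distinct windows")
  best <- withr::with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- kmedians_once(X, k, max_iter)
      if (is.null(best) || fit$cost < best$cost) best <- fit
    }
    best
  })
  # relabel by descending occurrence, deterministic tie-break on old label
  counts <- tabulate(best$labels, k)
  ord <- order(-counts, seq_len(k))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  labels <- relab[best$labels]
  centroids <- best$centroids[ord, , drop = FALSE]
  rownames(centroids) <- paste0("state", seq_len(k))
  model <- structure(list(k = k, centroids = centroids, labels = labels,
                          total_cost = best$cost, seed = seed),
                     class = "state_model")
  if (!is.null(subject)) {
    stopifnot(length(subject) == nrow(X))
    model$labels_by_subject <- split(labels, factor(subject, unique(subject)))
  }
  model
}

#' Mean silhouette width under the L1 distance
#'
#' Per-window silhouette `s = (b - a) / max(a, b)` with `a` the mean
#' intra-cluster distance and `b` the smallest mean distance to another
#' cluster; windows in singleton clusters score 0.
#'
#' @param X windows x edges matrix (ignored when `D` is supplied).
#' @param labels integer cluster labels.
#' @param D optional precomputed full distance matrix.
#' @return list with `mean` and per-window `widths`.
#' @export
silhouette_l1 <- function(X, labels, D = NULL) {
  if (is.null(D)) D <- as.matrix(stats::dist(X, method = "manhattan"))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  G <- matrix(0, n, k)
  for (j in seq_len(k))
    G[, j] <- rowSums(D[, labels == j, drop = FALSE])
  a <- G[cbind(seq_len(n), labels)] / pmax(sizes[labels] - 1, 1)
  Gm <- sweep(G, 2, sizes, "/")
  Gm[cbind(seq_len(n), labels)] <- Inf
  b <- apply(Gm, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  list(mean = mean(s), widths = s)
}

#' Select the number of states by the silhouette criterion
#'
#' Fits [cluster_windows()] for every candidate `k` and returns the `k`
#' maximising the mean L1 silhouette. Candidates whose fit fails are recorded
#' as `NA` and excluded from the argmax.
#'
#' @param X pooled windows x edges matrix.
#' @param k_range candidate state counts (default 2:8).
#' @param n_init restarts per candidate (default 100).
#' @param seed integer seed.
#' @param subject optional subject id per row, forwarded to the winning model.
#' @return list with `k_best`, `silhouette_by_k` (named vector), `model`
#'   (fitted model at `k_best`).
#' @export
select_k <- function(X, k_range = 2:8, n_init = 100, seed = 1L, subject = NULL) {
  X <- as.matrix(X)
  stopifnot(max(k_range) < nrow(X))
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- try(cluster_windows(X, k_range[i], n_init = n_init,
                               seed = seed + k_range[i], subject = subject),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    models[[i]] <- fit
    sil[i] <- silhouette_l1(labels = fit$labels, D = D)$mean
  }
  if (all(is.na(sil))) stop("no candidate k could be fitted")
  best <- which.max(sil)
  list(k_best = k_range[best], silhouette_by_k = sil, model = models[[best]])
}

#' Subject-specific state centroids
#'
#' The subject centroid of state m is the component-wise median of that
#' subject's windows labelled m; states a subject never visits are `NA` rows.
#'
#' @param X pooled windows x edges matrix.
#' @param labels pooled state labels.
#' @param subject subject id per row.
#' @param k number of states.
#' @return named list of k x edges matrices, one per subject.
#' @export
subject_state_centroids <- function(X, labels, subject, k) {
  stopifnot(nrow(X) == length(labels), length(subject) == length(labels))
  ids <- unique(subject)
  out <- lapply(ids, function(id) {
    sel <- subject == id
    M <- matrix(NA_real_, k, ncol(X))
    for (m in seq_len(k)) {
      rows <- sel & labels == m
      if (any(rows)) M[m, ] <- colMedians(X[rows, , drop = FALSE])
    }
    rownames(M) <- paste0("state", seq_len(k))
    colnames(M) <- colnames(X)
    M
  })
  stats::setNames(out, ids)
}

#' Group-level state centroids
#'
#' Arithmetic mean of the defined subject centroids per group; a state no
#' subject of a group visits yields an `NA` row with a warning.
#'
#' @param subject_centroids result of [subject_state_centroids()].
#' @param groups named character vector or data frame (`subject_id`, `group`)
#'   mapping subjects to groups.
#' @return named list of k x edges matrices, one per group.
#' @export
group_state_centroids <- function(subject_centroids, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$subject_id)
  ids <- names(subject_centroids)
  stopifnot(all(ids %in% names(groups)))
  out <- lapply(unique(groups[ids]), function(g) {
    mats <- subject_centroids[ids[groups[ids] == g]]
    k <- nrow(mats[[1]])
    M <- matrix(NA_real_, k, ncol(mats[[1]]), dimnames = dimnames(mats[[1]]))
    for (m in seq_len(k)) {
      rows <- do.call(rbind, lapply(mats, function(x) x[m, ]))
      ok <- stats::complete.cases(rows)
      if (!any(ok)) {
        warning(sprintf("state %d visited by no subject in group %s", m, g))
      } else {
        M[m, ] <- colMeans(rows[ok, , drop = FALSE])
      }
    }
    M
  })
  stats::setNames(out, unique(groups[ids]))
}

#' Fractional windows (state occupancy)
#'
#' @param labels state-label sequence (values in 1..k).
#' @param k number of states.
#' @return length-k vector of occupancy proportions, summing to 1.
#' @export
fractional_windows <- function(labels, k) {
  stopifnot(length(labels) >= 1, all(labels %in% seq_len(k)))
  tabulate(labels, k) / length(labels)
}

#' Mean dwell time per state
#'
#' Average length of maximal runs of consecutive windows in each state (the
#' final, uninterrupted run counts); 0 for states never visited. Reported in
#' window units.
#'
#' @inheritParams fractional_windows
#' @return length-k vector.
#' @export
mean_dwell_time <- function(labels, k) {
  stopifnot(length(labels) >= 1, all(labels %in% seq_len(k)))
  r <- rle(labels)
  vapply(seq_len(k), function(m) {
    len <- r$lengths[r$values == m]
    if (length(len) == 0) 0 else mean(len)
  }, 0)
}

#' Number of state transitions
#'
#' @param labels state-label sequence.
#' @return count of consecutive pairs with differing labels.
#' @export
n_transitions <- function(labels) {
  stopifnot(length(labels) >= 1)
  sum(labels[-1] != labels[-length(labels)])
}

#' Empirical transition-likelihood matrix
#'
#' Entry (a, b) is the fraction of consecutive window pairs starting in state
#' a that move to state b (self-transitions included). Rows for states with
#' no outgoing pair are `NA` (undefined) and should be excluded from group
#' statistics.
#'
#' @inheritParams fractional_windows
#' @return k x k matrix; defined rows sum to 1.
#' @export
transition_likelihood <- function(labels, k) {
  stopifnot(length(labels) >= 2, all(labels %in% seq_len(k)))
  from <- labels[-length(labels)]
  to <- labels[-1]
  M <- matrix(0, k, k)
  for (i in seq_along(from)) M[from[i], to[i]] <- M[from[i], to[i]] + 1
  sum_rows <- rowSums(M)
  M <- M / ifelse(sum_rows > 0, sum_rows, 1)
  M[sum_rows == 0, ] <- NA_real_
  M
}

#' All four temporal properties of a label sequence
#'
#' @inheritParams fractional_windows
#' @return list with `fractional_windows`, `mean_dwell`, `n_transitions`,
#'   `transition_likelihood`.
#' @export
temporal_metrics <- function(labels, k) {
  list(fractional_windows = fractional_windows(labels, k),
       mean_dwell = mean_dwell_time(labels, k),
       n_transitions = n_transitions(labels),
       transition_likelihood = transition_likelihood(labels, k))
}

# all injective assignments of rows to columns maximising total score
best_assignment <- function(R) {
  ka <- nrow(R); kb <- ncol(R)
  swap <- FALSE
  if (ka > kb) { R <- t(R); tmp <- ka; ka <- kb; kb <- tmp; swap <- TRUE }
  best <- list(score = -Inf, cols = NULL)
  rec <- function(row, used, score, cols) {
    if (row > ka) {
      if (score > best$score) best <<- list(score = score, cols = cols)
      return()
    }
    for (cc in setdiff(seq_len(kb), used))
      rec(row + 1, c(used, cc), score + R[row, cc], c(cols, cc))
  }
  rec(1, integer(0), 0, integer(0))
  pairs <- cbind(seq_len(ka), best$cols)
  if (swap) pairs <- pairs[, 2:1, drop = FALSE]
  pairs
}

#' Match and correlate centroids of two state models
#'
#' Computes Pearson correlations between every pair of centroid edge vectors
#' and the one-to-one state matching maximising total correlation; used to
#' check that states found under different window sizes agree.
#'
#' @param model_a,model_b `state_model` objects (or bare centroid matrices)
#'   over the same component set.
#' @return list with `r_matrix` (k_a x k_b) and `pairs` (data frame
#'   `state_a`, `state_b`, `r` for the `min(k_a, k_b)` matched pairs).
#' @export
centroid_similarity <- function(model_a, model_b) {
  A <- if (inherits(model_a, "state_model")) model_a$centroids else as.matrix(model_a)
  B <- if (inherits(model_b, "state_model")) model_b$centroids else as.matrix(model_b)
  stopifnot(ncol(A) == ncol(B))
  R <- stats::cor(t(A), t(B))
  pairs <- best_assignment(R)
  data_pairs <- data.frame(state_a = pairs[, 1], state_b = pairs[, 2],
                           r = R[pairs])
  list(r_matrix = R, pairs = data_pairs[order(data_pairs$state_a), ])
}

#' Window-level truth labels by majority vote
#'
#' Discretises a timepoint-resolution state sequence to window resolution:
#' each window's truth label is the modal state among the timepoints it
#' covers (ties broken towards the lower state index).
#'
#' @param labels timepoint-level state labels.
#' @param window_len window length in TRs.
#' @param step window step (default 1).
#' @return integer labels, one per window (same windowing as
#'   [window_starts()]).
#' @export
majority_vote_labels <- function(labels, window_len, step = 1) {
  starts <- window_starts(length(labels), window_len, step)
  vapply(starts, function(s0) {
    win <- labels[(s0 + 1):(s0 + window_len)]
    which.max(tabulate(win))
  }, 0L)
}
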