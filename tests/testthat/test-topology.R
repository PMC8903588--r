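test_that("binarization keeps the strongest positive edges at the target count", {
  # 4 nodes, 6 distinct positive edges, sparsity 0.5 -> top 3 kept
  v <- c(0.9, 0.1, 0.5, 0.3, 0.8, 0.2)  # edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  g <- binarize_at_sparsity(edges_to_mat(v, 4), 0.5)
  expect_equal(g$n_edges, 3)
  expect_equal(mat_to_edges(g$adjacency), c(1, 0, 1, 0, 1, 0))
  expect_false(g$flagged)

  # only positive values are eligible
  g_neg <- binarize_at_sparsity(edges_to_mat(-v, 4), 0.5)
  expect_equal(g_neg$n_edges, 0)
  expect_true(g_neg$flagged)

  # near-1 sparsity on an all-positive matrix: complete graph
  g_full <- binarize_at_sparsity(edges_to_mat(v, 4), 0.999)
  expect_equal(g_full$n_edges, 6)

  # rank-based: any strictly monotone transform leaves the graph unchanged
  g2 <- binarize_at_sparsity(edges_to_mat(2 * v, 4), 0.5)
  expect_equal(g2$adjacency, g$adjacency)
  # ties broken by lexicographic edge index
  vt <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  gt <- binarize_at_sparsity(edges_to_mat(vt, 4), 0.5)
  expect_equal(mat_to_edges(gt$adjacency), c(1, 1, 1, 0, 0, 0))
})

test_that("efficiency and path metrics match hand-computed small graphs", {
  K4 <- as_binary_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(global_efficiency(K4), 1)
  expect_equal(nodal_efficiency(K4), rep(1, 4))
  expect_equal(local_efficiency(K4), 1)

  # path graph 1-2-3
  P3 <- as_binary_graph(edges_to_mat(c(1, 0, 1), 3))
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_equal(clustering_coefficient(P3), 0)
  expect_equal(characteristic_path_length(P3), 4 / 3)

  # star on 4 nodes, centre first
  S4 <- as_binary_graph(edges_to_mat(c(1, 1, 1, 0, 0, 0), 4))
  ne <- nodal_efficiency(S4)
  expect_equal(ne[1], 1)
  expect_equal(ne[2:4], rep(2 / 3, 3))

  # triangle
  T3 <- as_binary_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(clustering_coefficient(T3), 1)
  expect_equal(characteristic_path_length(T3), 1)
  expect_equal(local_efficiency(T3), 1)

  # empty graph: L undefined
  E3 <- as_binary_graph(matrix(0, 3, 3))
  expect_true(is.na(characteristic_path_length(E3)))
})

test_that("small-world metrics are consistent and lattice-like graphs are clustered", {
  K5 <- as_binary_graph(matrix(1, 5, 5) - diag(5))
  sw <- small_world_metrics(K5, n_random = 5, seed = 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # ring lattice n = 30, k = 4 neighbours
  n <- 30
  A <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  lat <- as_binary_graph(A)
  sw <- small_world_metrics(lat, n_random = 20, seed = 2)
  # lattices are far more clustered than degree-matched random graphs, and
  # that excess dominates their longer paths: gamma >> 1, gamma > lambda
  expect_gt(sw$gamma, 1.5)
  expect_lt(sw$lambda, sw$gamma)
  expect_gt(sw$sigma, 1)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
})

test_that("AUC over thresholds is an exact trapezoid", {
  prof <- threshold_profile()
  expect_equal(auc_over_thresholds(rep(2, 26), prof), 0.25 * 2,
               tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 26)
  expect_equal(auc_over_thresholds(ramp, prof), 0.125, tolerance = 1e-12)
  set.seed(31)
  vals <- runif(26)
  s <- prof$sparsities
  hand <- sum(vapply(1:25, function(i)
    (s[i + 1] - s[i]) * (vals[i] + vals[i + 1]) / 2, 0))
  expect_equal(auc_over_thresholds(vals, prof), hand, tolerance = 1e-12)
  # isolated undefined values are interpolated
  vals_na <- vals
  vals_na[10] <- NA
  interp <- vals
  interp[10] <- (vals[9] + vals[11]) / 2
  expect_equal(auc_over_thresholds(vals_na, prof),
               auc_over_thresholds(interp, prof), tolerance = 1e-12)
  expect_true(is.na(auc_over_thresholds(rep(NA_real_, 26), prof)))
  expect_error(auc_over_thresholds(1:5, prof), "one value per threshold")
})

test_that("coefficient of variation follows both definitions", {
  expect_equal(cv_over_windows(rep(3, 10)), 0)
  expect_equal(cv_over_windows(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cv_over_windows(c(1, 3), "mean_over_sd"), sqrt(2),
               tolerance = 1e-12)
  expect_true(is.na(cv_over_windows(c(-1, 1))))          # zero mean
  expect_true(is.na(cv_over_windows(rep(2, 5), "mean_over_sd")))  # zero SD
})

test_that("dynamic topology profiles are rank-invariant and zero-CV for static series", {
  set.seed(32)
  base <- edges_to_mat(runif(15, -0.2, 0.8), 6)
  series <- fake_window_series(list(base, base, base))
  prof <- threshold_profile(0.2, 0.4, 0.1)
  tp <- dynamic_topology(series, prof, n_random = 3, seed = 5)
  expect_equal(unname(tp$cv[c("E_g", "E_loc", "C", "L")]), rep(0, 4))
  expect_equal(tp$nodal_cv, rep(0, 6))

  # doubling z leaves the whole profile unchanged (thresholding is rank-based)
  series2 <- fake_window_series(list(2 * base, 2 * base, 2 * base))
  tp2 <- dynamic_topology(series2, prof, n_random = 3, seed = 5)
  expect_equal(tp2$auc, tp$auc)
  expect_equal(tp2$nodal_auc, tp$nodal_auc)
})

test_that("dynamic topology AUC matches an oracle computation on a toy series", {
  set.seed(33)
  mats <- list(edges_to_mat(runif(15, 0.1, 1), 6),
               edges_to_mat(runif(15, 0.1, 1), 6))
  series <- fake_window_series(mats)
  prof <- threshold_profile(0.2, 0.5, 0.1)
  tp <- dynamic_topology(series, prof, n_random = 2, seed = 7)
  for (w in 1:2) {
    vals <- sapply(prof$sparsities, function(sp) {
      A <- binarize_at_sparsity(mats[[w]], sp)$adjacency
      c(oracle_global_efficiency(A), oracle_local_efficiency(A),
        oracle_clustering(A), oracle_path_length(A))
    })
    s <- prof$sparsities
    trapz <- function(v) sum(diff(s) * (head(v, -1) + tail(v, -1)) / 2)
    expect_equal(unname(tp$auc[w, "E_g"]), trapz(vals[1, ]), tolerance = 1e-10)
    expect_equal(unname(tp$auc[w, "E_loc"]), trapz(vals[2, ]), tolerance = 1e-10)
    expect_equal(unname(tp$auc[w, "C"]), trapz(vals[3, ]), tolerance = 1e-10)
    expect_equal(unname(tp$auc[w, "L"]), trapz(vals[4, ]), tolerance = 1e-10)
  }
})
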