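test_that("taper weights match a direct convolution oracle", {
  # near-delta kernel: rectangle essentially unchanged
  tp <- build_taper(10, sigma = 1e-6)
  expect_equal(tp$weights, rep(1, 10), tolerance = 1e-6)

  tp <- build_taper(20, 3)
  expect_equal(tp$weights, rev(tp$weights), tolerance = 1e-12)
  expect_gt(tp$weights[10], tp$weights[1])

  for (case in list(c(20, 3), c(16, 3), c(7, 1.5), c(30, 5))) {
    got <- build_taper(case[1], case[2])$weights
    expect_equal(got, oracle_taper(case[1], case[2]), tolerance = 1e-12)
  }
})

test_that("window starts follow the floor((T - w)/step) convention", {
  s <- window_starts(170, 20, 1)
  expect_length(s, 150)
  expect_equal(s[1], 0L)
  expect_equal(s[150], 149L)
  expect_length(window_starts(21, 20, 1), 1)
  expect_length(window_starts(170, 16, 1), 154)
  expect_length(window_starts(170, 24, 1), 146)
  # cross-check against direct enumeration for assorted (T, w, step)
  for (case in list(c(100, 10, 2), c(57, 8, 3), c(170, 20, 5))) {
    got <- window_starts(case[1], case[2], case[3])
    enum <- seq(0, case[1] - case[2] - 1, by = case[3])
    enum <- enum[seq_len(floor((case[1] - case[2]) / case[3]))]
    expect_equal(got, as.integer(enum))
  }
  expect_error(window_starts(20, 20, 1), "exceed")
})

test_that("a 20-TR window at TR 2 s lasts 40 s", {
  expect_equal(window_duration_s(20, 2), 40)
})

test_that("graphical lasso satisfies its optimality conditions", {
  set.seed(10)
  # KKT: |Sigma_hat_ij - S_ij| <= lambda off the diagonal
  for (rep in 1:5) {
    p <- sample(3:8, 1)
    X <- matrix(rnorm(60 * p), 60, p)
    S <- cov(X)
    lam <- runif(1, 0.02, 0.3)
    fit <- graphical_lasso(S, lam)
    expect_true(fit$converged)
    dev <- abs(fit$covariance - S)
    expect_lt(max(dev[upper.tri(dev)]), lam + 1e-3)
    # on the support the bound is tight
    supp <- abs(fit$precision) > 1e-6 & upper.tri(S)
    if (any(supp)) expect_gt(min(dev[supp]), lam - 1e-3)
  }
})

test_that("windowed connectivity recovers the sample correlation in the unpenalised limit", {
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  X[, 2] <- 0.5 * X[, 1] + sqrt(0.75) * X[, 2]
  tc <- time_course_matrix(X, 2)
  # uniform taper via near-delta sigma
  taper <- build_taper(40, sigma = 1e-6)
  ws <- windowed_fc(tc, taper, step = 1, lasso_penalty = 1e-6)
  for (i in seq_along(ws$window_starts)) {
    idx <- (ws$window_starts[i] + 1):(ws$window_starts[i] + 40)
    r <- cor(X[idx, 1], X[idx, 2])
    expect_equal(ws$z_matrices[[i]][1, 2], atanh(r), tolerance = 1e-3)
  }
})

test_that("heavy penalisation forces uncorrelated estimates and contracts hold", {
  set.seed(12)
  X <- matrix(rnorm(200), 100, 2)
  tc <- time_course_matrix(X, 2)
  taper <- build_taper(30, 3)
  ws <- windowed_fc(tc, taper, lasso_penalty = 5)
  for (z in ws$z_matrices) {
    expect_equal(z[1, 2], 0, tolerance = 1e-4)
    expect_equal(z, t(z))
    expect_equal(diag(z), rep(0, 2))
    expect_true(all(is.finite(z)))
  }
})

test_that("edge vectorisation is row-major upper triangle and invertible", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 0  # fill explicitly below
  vals <- c(12, 13, 14, 23, 24, 34)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (i in seq_len(6)) {
    m[pairs[i, 1], pairs[i, 2]] <- vals[i]
    m[pairs[i, 2], pairs[i, 1]] <- vals[i]
  }
  expect_equal(mat_to_edges(m), vals)
  expect_equal(edges_to_mat(vals, 4), m)
  expect_equal(edge_labels(c("C1", "C2", "C3", "C4")),
               c("C1_C2", "C1_C3", "C1_C4", "C2_C3", "C2_C4", "C3_C4"))
})

test_that("penalty selection is reproducible and respects a singleton grid", {
  set.seed(13)
  X <- matrix(rnorm(80 * 4), 80, 4)
  tc <- time_course_matrix(X, 2)
  taper <- build_taper(20, 3)
  expect_equal(select_lasso_penalty(tc, taper, 0.1, n_repetitions = 3)$lambda, 0.1)
  a <- select_lasso_penalty(tc, taper, c(0.05, 0.2), n_repetitions = 5, seed = 4)
  b <- select_lasso_penalty(tc, taper, c(0.05, 0.2), n_repetitions = 5, seed = 4)
  expect_identical(a, b)
})

test_that("penalty selection recovers sparsity structure from sparse-precision data", {
  # chain-structured precision (only |i-j| <= 1 nonzero) in a
  # samples-starved regime: 5 non-overlapping 15-sample windows of 12
  # components, so held-out likelihood genuinely rewards regularisation
  set.seed(14)
  p <- 12
  Theta <- diag(p)
  for (i in 1:(p - 1)) Theta[i, i + 1] <- Theta[i + 1, i] <- 0.4
  L <- chol(solve(Theta))
  X <- matrix(rnorm(75 * p), 75, p) %*% L
  tc <- time_course_matrix(X, 2)
  taper <- build_taper(15, 3)
  grid <- c(0.01, 0.05, 0.15, 0.4)
  sel <- select_lasso_penalty(tc, taper, grid, n_repetitions = 20,
                              step = 15, seed = 5)
  expect_gt(sel$lambda, min(grid))  # the unregularised end loses
  fit <- graphical_lasso(cov(X), sel$lambda)
  truly_zero <- abs(Theta) < 1e-12 & upper.tri(Theta)
  est_zero <- abs(fit$precision) < 1e-4
  expect_gte(mean(est_zero[truly_zero]), 0.9)
})

test_that("covariate residualisation removes age effects and preserves means", {
  set.seed(15)
  n_sub <- 40
  n_comp <- 4
  age <- rnorm(n_sub, 50, 10)
  sex <- rep(c(0, 1), n_sub / 2)
  series <- lapply(seq_len(n_sub), function(i) {
    mats <- lapply(1:5, function(w) {
      v <- 0.01 * age[i] + rnorm(6, sd = 0.05)
      edges_to_mat(v, n_comp)
    })
    fake_window_series(mats, sprintf("sub-%03d", i))
  })
  cov_df <- data.frame(subject_id = sprintf("sub-%03d", 1:n_sub),
                       age = age, sex = sex)
  before <- t(vapply(series, function(s) colMeans(window_edge_matrix(s)),
                     numeric(6)))
  out <- residualize_connectivity(series, cov_df)
  after <- t(vapply(out, function(s) colMeans(window_edge_matrix(s)),
                    numeric(6)))
  # age relationship removed
  for (e in 1:6) expect_lt(abs(cor(after[, e], age)), 0.05)
  # grand mean preserved edge by edge
  expect_equal(colMeans(after), colMeans(before), tolerance = 1e-10)
  # diagonal stays zero
  expect_equal(diag(out[[1]]$z_matrices[[1]]), rep(0, n_comp))
})

test_that("constant covariates are dropped with a warning and leave data unchanged", {
  set.seed(16)
  series <- lapply(1:6, function(i)
    fake_window_series(lapply(1:3, function(w) edges_to_mat(rnorm(3), 3)),
                       sprintf("sub-%03d", i)))
  cov_df <- data.frame(subject_id = sprintf("sub-%03d", 1:6),
                       age = rep(50, 6), sex = rep(1, 6))
  expect_warning(out <- residualize_connectivity(series, cov_df), "constant")
  expect_equal(out[[3]]$z_matrices, series[[3]]$z_matrices)
})
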