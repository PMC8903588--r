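make_tc <- function(values, tr = 2) time_course_matrix(as.matrix(values), tr)

test_that("framewise displacement matches closed-form cases", {
  n <- 10
  zero <- motion_trace(matrix(0, n, 3), matrix(0, n, 3))
  expect_equal(framewise_displacement(zero), rep(0, n))

  # pure step translation: FD equals the Euclidean step size, only at the step
  tr <- matrix(0, n, 3); tr[5:n, 1] <- 0.2
  fd <- framewise_displacement(motion_trace(tr, matrix(0, n, 3)))
  expect_equal(fd[5], 0.2, tolerance = 1e-12)
  expect_equal(fd[-5], rep(0, n - 1))

  # small rotation step about one axis: FD ~ R * theta * sqrt(2/5)
  theta <- 1e-3
  for (axis in 1:3) {
    rot <- matrix(0, n, 3); rot[5:n, axis] <- theta
    fd <- framewise_displacement(motion_trace(matrix(0, n, 3), rot))
    expect_equal(fd[5], 80 * theta * sqrt(2 / 5), tolerance = 1e-6)
  }
})

test_that("framewise displacement agrees with a Monte Carlo sphere-average oracle", {
  set.seed(42)
  tr <- matrix(rnorm(2 * 3, sd = 0.3), 2, 3)
  rot <- matrix(rnorm(2 * 3, sd = 0.02), 2, 3)
  m <- motion_trace(tr, rot)
  fd <- framewise_displacement(m)

  # oracle: RMS displacement of points uniform in the 80 mm ball
  T1 <- dynconn:::rigid_transform(tr[1, ], rot[1, ])
  T2 <- dynconn:::rigid_transform(tr[2, ], rot[2, ])
  M <- T2 %*% solve(T1) - diag(4)
  npts <- 2e5
  pts <- matrix(rnorm(3 * npts), 3)
  pts <- pts / rep(sqrt(colSums(pts^2)), each = 3) *
    rep(80 * runif(npts)^(1 / 3), each = 3)
  disp <- M[1:3, 1:3] %*% pts + M[1:3, 4]
  expect_equal(fd[2], sqrt(mean(colSums(disp^2))), tolerance = 0.01)
})

test_that("FD is invariant to a constant translation offset when rotations are fixed", {
  set.seed(1)
  tr <- matrix(cumsum(rnorm(60, sd = 0.05)), 20, 3)
  rot <- matrix(0.01, 20, 3)  # constant rotations
  fd1 <- framewise_displacement(motion_trace(tr, rot))
  fd2 <- framewise_displacement(motion_trace(tr + 5, rot))
  expect_equal(fd1, fd2, tolerance = 1e-10)
})

test_that("QC exclusion applies strict thresholds rule by rule", {
  n <- 20
  mk <- function(fd_level, trans, rot_deg) {
    tr <- matrix(0, n, 3); tr[2, 1] <- trans
    ro <- matrix(0, n, 3); ro[2, 1] <- rot_deg * pi / 180
    list(fd = rep(fd_level, n), motion = motion_trace(tr, ro))
  }
  ok <- mk(0.19, 1.0, 1.0)
  rep1 <- qc_exclude(ok$fd, ok$motion)
  expect_false(rep1$excluded)
  expect_length(rep1$reasons, 0)

  high_fd <- mk(0.25, 1.0, 1.0)
  rep2 <- qc_exclude(high_fd$fd, high_fd$motion)
  expect_true(rep2$excluded)
  expect_equal(rep2$reasons, "mean_fd")

  # exactly at thresholds: retained (strict >)
  at <- mk(0.2, 1.5, 1.5)
  expect_false(qc_exclude(at$fd, at$motion)$excluded)

  both <- mk(0.3, 2.0, 2.0)
  expect_setequal(qc_exclude(both$fd, both$motion)$reasons,
                  c("mean_fd", "max_translation", "max_rotation"))
})

test_that("detrending removes polynomials of the requested order", {
  t <- 1:50
  expect_equal(detrend_timecourses(make_tc(rep(3, 50)), 0)$values[, 1],
               rep(0, 50), ignore_attr = TRUE)
  expect_equal(detrend_timecourses(make_tc(2 * t + 3), 1)$values[, 1],
               rep(0, 50), tolerance = 1e-10, ignore_attr = TRUE)
  # quadratic under a linear fit: equals the lm residual oracle
  y <- t^2
  got <- detrend_timecourses(make_tc(y), 1)$values[, 1]
  expect_equal(unname(got), unname(resid(lm(y ~ t))), tolerance = 1e-8)
  # output is mean-zero
  set.seed(2)
  out <- detrend_timecourses(make_tc(cbind(rnorm(50), rnorm(50))), 2)
  expect_lt(max(abs(colMeans(out$values))), 1e-10)
})

test_that("despiking compresses spikes but leaves smooth series untouched", {
  set.seed(3)
  t <- seq(0, 2 * pi, length.out = 120)
  smooth <- sin(t)
  out <- despike_timecourses(make_tc(smooth))
  expect_equal(out$values[, 1], smooth, tolerance = 1e-8, ignore_attr = TRUE)

  x <- sin(t) + rnorm(120, sd = 0.1)
  x_sp <- x
  x_sp[60] <- x[60] + 10 * mad(lm.fit(dynconn:::despike_basis(120), x)$residuals)
  out <- despike_timecourses(make_tc(x_sp))$values[, 1]
  # the spiked sample ends within c2 = 4 robust SDs of the fitted baseline
  fit_sp <- lm.fit(dynconn:::despike_basis(120), x_sp)
  baseline <- x_sp - fit_sp$residuals
  expect_lt(abs(out[60] - baseline[60]) / mad(fit_sp$residuals), 4)
  expect_lt(out[60], x_sp[60])  # the spike was actually compressed
  # flat series: returned unchanged
  flat <- rep(1.5, 120)
  expect_equal(despike_timecourses(make_tc(flat))$values[, 1], flat,
               ignore_attr = TRUE)
})

test_that("despike compression is monotone in input magnitude", {
  set.seed(4)
  t <- seq(0, 2 * pi, length.out = 120)
  x <- sin(t) + rnorm(120, sd = 0.1)
  mags <- seq(0, 12, by = 0.5)
  outs <- vapply(mags, function(m) {
    xs <- x
    xs[60] <- x[60] + m
    despike_timecourses(make_tc(xs))$values[60, 1]
  }, 0)
  expect_true(all(diff(outs) >= -1e-10))
})

test_that("butterworth low-pass matches the analytic magnitude response", {
  # constant series: DC gain 1
  const <- make_tc(rep(2.5, 200))
  expect_equal(lowpass_timecourses(const)$values[, 1], rep(2.5, 200),
               tolerance = 1e-8, ignore_attr = TRUE)

  gain_at <- function(f_hz, tr = 2, n = 4000) {
    t <- (1:n) * tr
    x <- sin(2 * pi * f_hz * t)
    y <- lowpass_timecourses(make_tc(x, tr))$values[, 1]
    mid <- (n / 4):(3 * n / 4)
    sd(y[mid]) / sd(x[mid])
  }
  expect_gte(gain_at(0.05), 0.99)
  # 0.20 Hz sits in the stop band: the digital (bilinear-transform) design
  # attenuates at least as strongly there as the analog two-pass magnitude
  # 1/(1+(0.2/0.15)^10) ~ 0.053 (frequency warping steepens the response
  # towards Nyquist)
  expect_lt(gain_at(0.20), 1 / (1 + (0.2 / 0.15)^10))
  expect_lt(gain_at(0.20), 0.01)
  expect_error(lowpass_timecourses(make_tc(rnorm(100), tr = 4), 0.15),
               "Nyquist")
})

test_that("nuisance regression produces residuals orthogonal to the design", {
  set.seed(5)
  n <- 100
  reg <- matrix(rnorm(n * 3), n, 3)
  # component equal to a regressor -> zero residual
  tc <- make_tc(reg[, 1])
  expect_lt(max(abs(regress_nuisance(tc, reg)$values)), 1e-10)
  # random case vs normal-equations oracle
  Y <- matrix(rnorm(n * 4), n, 4)
  got <- regress_nuisance(make_tc(Y), reg)$values
  X <- cbind(1, reg)
  expected <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(got), unname(expected), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(reg, got))), 1e-8 * n)
  # collinear design errors
  expect_error(regress_nuisance(make_tc(Y), cbind(reg, reg[, 1])),
               "rank-deficient")
})

test_that("low-frequency power ratio separates slow from fast components", {
  tr <- 2
  t <- (1:160) * tr
  slow <- sin(2 * pi * 0.05 * t)
  fast <- sin(2 * pi * 0.20 * t)
  r_slow <- low_freq_power_ratio(slow, tr)
  expect_gt(r_slow$ratio, 1e6)
  expect_true(r_slow$undefined)
  r_fast <- low_freq_power_ratio(fast, tr)
  expect_lt(r_fast$ratio, 1e-6)
  mix <- slow + fast
  r_mix <- low_freq_power_ratio(mix, tr)
  expect_equal(r_mix$ratio, 1, tolerance = 0.1)
})

test_that("preprocessing stages commute with component permutation", {
  set.seed(6)
  X <- matrix(rnorm(100 * 4), 100, 4) + outer(1:100, c(0.01, 0, -0.02, 0.03))
  perm <- c(3, 1, 4, 2)
  out <- preprocess_timecourses(make_tc(X))$values
  out_perm <- preprocess_timecourses(make_tc(X[, perm]))$values
  expect_equal(unname(out_perm), unname(out[, perm]), tolerance = 1e-10)
})

test_that("detrending and nuisance regression are idempotent", {
  set.seed(7)
  X <- matrix(rnorm(80 * 3), 80, 3)
  reg <- matrix(rnorm(80 * 2), 80, 2)
  d1 <- detrend_timecourses(make_tc(X), 1)
  d2 <- detrend_timecourses(d1, 1)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
  r1 <- regress_nuisance(make_tc(X), reg)
  r2 <- regress_nuisance(r1, reg)
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("initial volumes are discarded in step with the motion trace", {
  tc <- make_tc(matrix(rnorm(180 * 3), 180, 3))
  mo <- motion_trace(matrix(rnorm(180 * 3), 180, 3) * 0.01,
                     matrix(0, 180, 3))
  out <- discard_initial_volumes(tc, 10, mo)
  expect_equal(nrow(out$tc$values), 170)
  expect_equal(nrow(out$motion$translations_mm), 170)
  expect_equal(out$tc$values[1, ], tc$values[11, ])
})
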