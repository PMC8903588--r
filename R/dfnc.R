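#' Tapered sliding-window weights
#'
#' Discrete convolution of a rectangle of `window_len` ones with a unit-area
#' Gaussian kernel of standard deviation `sigma` (in TR units), truncated to
#' the central `window_len` samples. The taper is symmetric with its maximum
#' at the centre; as `sigma -> 0` it tends to the plain rectangular window.
#'
#' @param window_len window length in TRs (>= 2).
#' @param sigma Gaussian standard deviation in TRs (default 3).
#' @return object of class `taper_weights` with fields `weights`,
#'   `window_len_tr`, `gaussian_sigma_tr`.
#' @export
build_taper <- function(window_len, sigma = 3) {
  stopifnot(window_len >= 2, sigma > 0)
  half <- max(1L, ceiling(4 * sigma))
  k <- (-half):half
  g <- exp(-k^2 / (2 * sigma^2))
  g <- g / sum(g)
  rect <- rep(1, window_len)
  full <- stats::convolve(rect, rev(g), type = "open")  # length window_len + 2*half
  start <- half + 1
  w <- full[start:(start + window_len - 1)]
  w <- (w + rev(w)) / 2  # enforce exact symmetry against fft round-off
  structure(list(weights = w, window_len_tr = as.integer(window_len),
                 gaussian_sigma_tr = sigma), class = "taper_weights")
}

#' Sliding-window start offsets
#'
#' Returns 0-based window offsets `0, step, 2*step, ...`; the number of
#' windows is `floor((n_timepoints - window_len) / step)`, so 170 timepoints
#' with a 20-TR window and 1-TR step give exactly 150 windows. Window `i`
#' covers samples `[offset_i, offset_i + window_len)`. Note the final fully
#' contained window is intentionally not emitted (count is `T - w`, not
#' `T - w + 1`), matching the windowing convention this count reproduces.
#'
#' @param n_timepoints series length.
#' @param window_len window length in TRs.
#' @param step step in TRs (default 1).
#' @return integer vector of 0-based offsets.
#' @export
window_starts <- function(n_timepoints, window_len, step = 1) {
  stopifnot(step >= 1)
  if (n_timepoints <= window_len)
    stop("n_timepoints must exceed window_len")
  n_win <- floor((n_timepoints - window_len) / step)
  as.integer(seq(0, by = step, length.out = n_win))
}

#' Window duration in seconds
#'
#' @param window_len window length in TRs.
#' @param tr_seconds TR in seconds.
#' @return duration in seconds (e.g. 20 TR at TR = 2 s -> 40 s).
#' @export
window_duration_s <- function(window_len, tr_seconds) {
  stopifnot(window_len >= 1, tr_seconds > 0)
  window_len * tr_seconds
}

#' Sparse inverse-covariance estimation (graphical lasso)
#'
#' Maximises `log det(Theta) - tr(S Theta) - lambda * ||Theta_offdiag||_1`
#' by an ADMM iteration: the Theta update is a closed-form eigendecomposition
#' step, the Z update a soft-threshold of the off-diagonal entries. At the
#' solution the off-diagonal stationarity conditions
#' `|(Theta^-1)_ij - S_ij| <= lambda` hold, with equality on the support.
#'
#' @param S symmetric covariance matrix.
#' @param lambda nonnegative L1 penalty on off-diagonal precision entries.
#' @param rho initial ADMM step size (default 1; adapted during the run to
#'   balance primal and dual residuals).
#' @param tol convergence tolerance on primal/dual residuals, relative to the
#'   Frobenius norm of `S` (default 1e-5).
#' @param maxit maximum iterations (default 2000).
#' @param init optional warm start, a list with `Z` and `U` from a previous
#'   solution on nearby data (e.g. the preceding overlapping window).
#' @return list with `precision` (sparse Theta), `covariance` (its inverse),
#'   `iterations`, `converged`, and the warm-start state `Z`, `U`.
#' @export
graphical_lasso <- function(S, lambda, rho = 1, tol = 1e-5, maxit = 2000,
                            init = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), lambda >= 0)
  S <- (S + t(S)) / 2
  p <- nrow(S)
  if (is.null(init)) {
    Z <- diag(p)
    U <- matrix(0, p, p)
  } else {
    Z <- init$Z
    U <- init$U
  }
  Theta <- Z
  converged <- FALSE
  it <- 0
  scale_ref <- max(1, norm(S, "F"))
  while (it < maxit) {
    it <- it + 1
    E <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (E$values + sqrt(E$values^2 + 4 * rho)) / (2 * rho)
    Theta <- E$vectors %*% (d * t(E$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - lambda / rho, 0)
    diag(Z) <- diag(A)
    U <- U + Theta - Z
    r_norm <- norm(Theta - Z, "F")
    s_norm <- rho * norm(Z - Zold, "F")
    if (r_norm < tol * scale_ref && s_norm < tol * scale_ref) {
      converged <- TRUE
      break
    }
    # residual balancing keeps the two residuals within a factor of 10
    if (r_norm > 10 * s_norm) {
      rho <- rho * 2
      U <- U / 2
    } else if (s_norm > 10 * r_norm) {
      rho <- rho / 2
      U <- U * 2
    }
  }
  Theta <- (Theta + t(Theta)) / 2
  list(precision = (Z + t(Z)) / 2, covariance = solve(Theta),
       iterations = it, converged = converged, Z = Z, U = U)
}

# Taper-weighted sample covariance of one window (rows = samples).
weighted_window_cov <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc * sqrt(w))  # sum_t w_t xc xc', weights sum to 1
}

#' Tapered sliding-window connectivity series
#'
#' For every window: form the taper-weighted sample covariance of the demeaned
#' window samples, estimate a sparse precision matrix by [graphical_lasso()],
#' invert it, convert to correlation, and Fisher-z transform the off-diagonals
#' (`atanh` of correlations clamped at `1 - 1e-7`); the diagonal is set to 0.
#'
#' @param tc a cleaned [time_course_matrix()].
#' @param taper a [build_taper()] result.
#' @param step window step in TRs (default 1).
#' @param lasso_penalty graphical-lasso penalty (default 0.1).
#' @param tol,maxit solver controls passed to [graphical_lasso()].
#' @return object of class `window_series`: `subject_id`, `z_matrices` (list
#'   of symmetric zero-diagonal matrices), `window_starts` (0-based), `params`.
#' @export
windowed_fc <- function(tc, taper, step = 1, lasso_penalty = 0.1,
                        tol = 1e-6, maxit = 1000) {
  stopifnot(inherits(tc, "time_course_matrix"), inherits(taper, "taper_weights"),
            lasso_penalty > 0)
  w <- taper$window_len_tr
  starts <- window_starts(nrow(tc$values), w, step)
  zmats <- vector("list", length(starts))
  warm <- NULL  # consecutive windows overlap heavily; warm-start the solver
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):(starts[i] + w)
    S <- weighted_window_cov(tc$values[idx, , drop = FALSE], taper$weights)
    fit <- graphical_lasso(S, lasso_penalty, tol = tol, maxit = maxit,
                           init = warm)
    warm <- fit[c("Z", "U")]
    if (!fit$converged)
      stop(sprintf("graphical lasso did not converge in window %d (subject %s)",
                   i, tc$subject_id))
    R <- stats::cov2cor(fit$covariance)
    R <- pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7)
    Z <- atanh(R)
    Z <- (Z + t(Z)) / 2
    diag(Z) <- 0
    zmats[[i]] <- Z
  }
  structure(list(subject_id = tc$subject_id, z_matrices = zmats,
                 window_starts = starts,
                 component_ids = tc$component_ids,
                 params = list(window_len = w, step = step,
                               taper_sigma = taper$gaussian_sigma_tr,
                               lasso_penalty = lasso_penalty)),
            class = "window_series")
}

#' Edge matrix of a window series
#'
#' @param series a [windowed_fc()] result.
#' @return numeric matrix, windows x edges, columns in [mat_to_edges()] order
#'   and labelled via [edge_labels()].
#' @export
window_edge_matrix <- function(series) {
  stopifnot(inherits(series, "window_series"))
  X <- t(vapply(series$z_matrices, mat_to_edges,
                numeric(length(mat_to_edges(series$z_matrices[[1]])))))
  colnames(X) <- edge_labels(series$component_ids)
  X
}

#' Pool windows across subjects
#'
#' @param series_list list of [windowed_fc()] results.
#' @return list with `X` (pooled windows x edges matrix), `subject`
#'   (subject id per row), `window` (within-subject window index per row).
#' @export
pool_windows <- function(series_list) {
  mats <- lapply(series_list, window_edge_matrix)
  X <- do.call(rbind, mats)
  subject <- rep(vapply(series_list, function(s) s$subject_id, ""),
                 vapply(mats, nrow, 0L))
  window <- unlist(lapply(mats, function(m) seq_len(nrow(m))))
  list(X = X, subject = subject, window = window)
}

#' Select the graphical-lasso penalty by cross-validated likelihood
#'
#' For each of `n_repetitions` random half-splits of the subject's windows,
#' fits a precision matrix per candidate penalty on the pooled (averaged)
#' train-window covariance and scores the mean Gaussian log-likelihood
#' `log det(Theta) - tr(S_w Theta)` over the held-out windows; returns the
#' candidate with the highest mean score across repetitions.
#'
#' @param tc a cleaned [time_course_matrix()].
#' @param taper a [build_taper()] result.
#' @param candidate_penalties numeric grid of penalties (> 0).
#' @param n_repetitions number of random splits (default 100).
#' @param step window step (default 1).
#' @param seed integer seed making the splits reproducible.
#' @return list with `lambda` (selected penalty) and `scores` (mean test
#'   log-likelihood per candidate).
#' @export
select_lasso_penalty <- function(tc, taper, candidate_penalties,
                                 n_repetitions = 100, step = 1, seed = 1L) {
  stopifnot(length(candidate_penalties) >= 1, all(candidate_penalties > 0),
            n_repetitions >= 1)
  w <- taper$window_len_tr
  starts <- window_starts(nrow(tc$values), w, step)
  covs <- lapply(starts, function(s0) {
    idx <- (s0 + 1):(s0 + w)
    weighted_window_cov(tc$values[idx, , drop = FALSE], taper$weights)
  })
  n_win <- length(covs)
  if (length(candidate_penalties) == 1)
    return(list(lambda = candidate_penalties, scores = NA_real_))
  scores <- withr::with_seed(seed, {
    acc <- matrix(0, n_repetitions, length(candidate_penalties))
    for (r in seq_len(n_repetitions)) {
      train <- sample.int(n_win, floor(n_win / 2))
      S_train <- Reduce(`+`, covs[train]) / length(train)
      for (li in seq_along(candidate_penalties)) {
        fit <- try(graphical_lasso(S_train, candidate_penalties[li]), silent = TRUE)
        if (inherits(fit, "try-error") || !fit$converged) {
          acc[r, li] <- NA_real_
          next
        }
        Theta <- solve(fit$covariance)
        ld <- determinant(Theta, logarithm = TRUE)$modulus
        acc[r, li] <- mean(vapply(covs[-train], function(Sw)
          as.numeric(ld - sum(Sw * Theta)), 0))
      }
    }
    colMeans(acc)
  })
  if (all(is.na(scores))) stop("no candidate penalty converged")
  list(lambda = candidate_penalties[which.max(scores)], scores = scores)
}

#' Residualise connectivity for age and sex
#'
#' For each edge independently, the subject-level mean z-value (across that
#' subject's windows) is regressed on mean-centred age and sex across
#' subjects; each subject's fitted covariate effect (not the intercept) is
#' subtracted from all of that subject's windows. The grand mean of every
#' edge is preserved and residualised subject means are uncorrelated with the
#' covariates.
#'
#' @param series_list list of [windowed_fc()] results, one per subject.
#' @param covariates data frame with `subject_id`, `age`, `sex` (one row per
#'   subject; `sex` numeric-codable). Constant columns are dropped with a
#'   warning.
#' @return list of `window_series` with adjusted z-matrices.
#' @export
residualize_connectivity <- function(series_list, covariates) {
  ids <- vapply(series_list, function(s) s$subject_id, "")
  stopifnot(all(ids %in% covariates$subject_id))
  covariates <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  Xc <- cbind(age = as.numeric(covariates$age), sex = as.numeric(covariates$sex))
  keep <- apply(Xc, 2, function(c) stats::sd(c) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(Xc)[!keep], collapse = ", "))
    Xc <- Xc[, keep, drop = FALSE]
  }
  if (ncol(Xc) == 0) return(series_list)
  Xc <- scale(Xc, center = TRUE, scale = FALSE)
  edge_means <- t(vapply(series_list, function(s)
    colMeans(window_edge_matrix(s)), numeric(length(mat_to_edges(series_list[[1]]$z_matrices[[1]])))))
  beta <- stats::lm.fit(cbind(1, Xc), edge_means)$coefficients
  effect <- Xc %*% beta[-1, , drop = FALSE]  # subjects x edges, mean zero
  n_comp <- length(series_list[[1]]$component_ids)
  for (i in seq_along(series_list)) {
    adj <- edges_to_mat(effect[i, ], n_comp)
    series_list[[i]]$z_matrices <- lapply(series_list[[i]]$z_matrices,
                                          function(m) { m2 <- m - adj; diag(m2) <- 0; m2 })
  }
  series_list
}
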