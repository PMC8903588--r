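#' Simulation configuration for a synthetic dFNC cohort
#'
#' Defines a two-group cohort of independent-component time courses whose
#' correlation structure switches between recurring covariance states under a
#' per-group Markov chain, plus realistic nuisance structure (white noise,
#' slow drift, spikes, head-motion traces) and demographic covariates.
#'
#' The defaults emulate the data layout the downstream analysis assumes:
#' 170 timepoints at TR = 2 s, two modular covariance states (one strongly
#' connected state with two modules at within-module correlation 0.7, one
#' sparsely connected uncorrelated state), and a patient-like group whose
#' transition matrix shifts long-run occupancy towards the sparse state
#' (~26% / 74%), against a control group nearer ~34% / 66%.
#'
#' @param n_subjects_per_group subjects per group (two groups).
#' @param n_components number of components (nodes).
#' @param n_timepoints timepoints per subject.
#' @param tr_seconds sampling interval in seconds.
#' @param state_covariances list of symmetric positive-definite matrices, or
#'   `NULL` to build them from `module_spec` via [make_state_covariances()].
#' @param module_spec per-state modular structure (see
#'   [make_state_covariances()]); ignored when `state_covariances` is given.
#' @param group_transition_matrices list of two row-stochastic matrices
#'   governing timepoint-level state switching, one per group.
#' @param observation_noise_sd SD of additive white noise.
#' @param drift_amplitude amplitude of the additive linear + 0.005-Hz
#'   sinusoidal drift.
#' @param spike_rate per-timepoint, per-component probability of an additive
#'   spike of amplitude 6 times the noise SD.
#' @param covariate_spec list with `age_mean`, `age_sd` (length-2, per group)
#'   and `sex_prop` (length-2 probability of sex code 1).
#' @param n_bad_subjects_per_group number of subjects per group whose motion
#'   trace is scaled to mean FD above the 0.2-mm exclusion threshold.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 10,
                       n_components = 20,
                       n_timepoints = 170,
                       tr_seconds = 2,
                       state_covariances = NULL,
                       module_spec = NULL,
                       group_transition_matrices = NULL,
                       observation_noise_sd = 0.2,
                       drift_amplitude = 0.5,
                       spike_rate = 0.005,
                       covariate_spec = NULL,
                       n_bad_subjects_per_group = 0,
                       seed = 1L) {
  stopifnot(n_subjects_per_group >= 1, n_components >= 2, n_timepoints >= 2,
            tr_seconds > 0, observation_noise_sd >= 0, drift_amplitude >= 0,
            spike_rate >= 0, spike_rate <= 1)
  if (is.null(state_covariances)) {
    if (is.null(module_spec)) {
      half <- c(rep(1L, ceiling(n_components / 2)),
                rep(2L, floor(n_components / 2)))
      module_spec <- list(
        list(modules = half, within = 0.7, between = 0),
        list(modules = rep(1L, n_components), within = 0, between = 0)
      )
    }
    state_covariances <- make_state_covariances(n_components, module_spec)
  }
  n_states <- length(state_covariances)
  stopifnot(n_states >= 2)
  for (s in state_covariances) {
    stopifnot(is.matrix(s), nrow(s) == n_components, ncol(s) == n_components)
    if (max(abs(s - t(s))) > 1e-10) stop("state covariance not symmetric")
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("state covariance not positive-definite")
  }
  if (is.null(group_transition_matrices)) {
    if (n_states != 2)
      stop("default transition matrices are defined for 2 states; supply group_transition_matrices")
    group_transition_matrices <- list(
      control = matrix(c(0.990, 0.010, 0.00504, 0.99496), 2, 2, byrow = TRUE),
      patient = matrix(c(0.980, 0.020, 0.00400, 0.99600), 2, 2, byrow = TRUE)
    )
  }
  stopifnot(length(group_transition_matrices) == 2)
  for (P in group_transition_matrices) validate_transition_matrix(P, n_states)
  if (is.null(covariate_spec)) {
    covariate_spec <- list(age_mean = c(50, 52), age_sd = c(10, 10),
                           sex_prop = c(0.5, 0.5))
  }
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_components = as.integer(n_components),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    n_states = as.integer(n_states),
    state_covariances = state_covariances,
    group_transition_matrices = group_transition_matrices,
    observation_noise_sd = observation_noise_sd,
    drift_amplitude = drift_amplitude,
    spike_rate = spike_rate,
    covariate_spec = covariate_spec,
    n_bad_subjects_per_group = as.integer(n_bad_subjects_per_group),
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_transition_matrix <- function(P, n_states = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (!is.null(n_states) && nrow(P) != n_states)
    stop("transition matrix dimension does not match number of states")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must be nonnegative and sum to 1")
  invisible(P)
}

#' Build modular state covariance matrices
#'
#' Each state is a correlation matrix with unit diagonal, `within` correlation
#' inside modules and `between` correlation across modules. If the naive block
#' matrix is not positive-definite it is shrunk towards the identity,
#' `(1-a)*C + a*I`, with the smallest `a` (in steps of 0.01) that makes the
#' smallest eigenvalue positive; the applied shrinkage is recorded in the
#' `"shrinkage"` attribute of each matrix.
#'
#' @param n_components number of components.
#' @param module_spec list with one element per state, each a list with
#'   `modules` (integer module assignment per component, or a single count of
#'   equally sized modules), `within` and `between` correlations in (-1, 1).
#' @param max_shrink maximal allowed shrinkage before erroring (default 0.9).
#' @return list of symmetric positive-definite matrices.
#' @export
make_state_covariances <- function(n_components, module_spec, max_shrink = 0.9) {
  stopifnot(n_components >= 1, length(module_spec) >= 1)
  lapply(module_spec, function(sp) {
    within <- sp$within
    between <- if (is.null(sp$between)) 0 else sp$between
    stopifnot(abs(within) < 1, abs(between) < 1)
    if (within < between)
      stop("within-module correlation must be >= between-module correlation")
    modules <- sp$modules
    if (length(modules) == 1) {
      modules <- rep(seq_len(modules), length.out = n_components)
      modules <- sort(modules)
    }
    stopifnot(length(modules) == n_components)
    same <- outer(modules, modules, "==")
    C <- ifelse(same, within, between)
    diag(C) <- 1
    shrink <- 0
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    while (ev <= 1e-10 && shrink < max_shrink) {
      shrink <- shrink + 0.01
      Cs <- (1 - shrink) * C + shrink * diag(n_components)
      ev <- min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values)
    }
    if (ev <= 1e-10)
      stop("infeasible correlation combination: not positive-definite even at maximal shrinkage")
    if (shrink > 0) C <- (1 - shrink) * C + shrink * diag(n_components)
    attr(C, "shrinkage") <- shrink
    C
  })
}

#' Sample a Markov state-label sequence
#'
#' @param transition_matrix row-stochastic matrix.
#' @param n_steps sequence length.
#' @param initial_distribution probability vector over states; defaults to the
#'   stationary distribution of the chain.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return integer vector of labels in `1..n_states`.
#' @export
sample_state_sequence <- function(transition_matrix, n_steps,
                                  initial_distribution = NULL, seed = NULL) {
  validate_transition_matrix(transition_matrix)
  stopifnot(n_steps >= 1)
  k <- nrow(transition_matrix)
  if (is.null(initial_distribution))
    initial_distribution <- stationary_distribution(transition_matrix)
  stopifnot(length(initial_distribution) == k,
            abs(sum(initial_distribution) - 1) < 1e-8)
  draw <- function() {
    labs <- integer(n_steps)
    labs[1] <- sample.int(k, 1, prob = initial_distribution)
    if (n_steps > 1) {
      for (t in 2:n_steps)
        labs[t] <- sample.int(k, 1, prob = transition_matrix[labs[t - 1], ])
    }
    labs
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Generate a synthetic two-group cohort with planted connectivity states
#'
#' For every subject a timepoint-level state sequence is drawn from the
#' subject's group transition matrix; each timepoint's component vector is a
#' zero-mean multivariate Gaussian draw under the active state's covariance.
#' White noise, a linear + 0.005-Hz sinusoidal drift, and sparse spikes
#' (amplitude 6 noise SDs) are added, and a smoothed random-walk motion trace
#' (typical mean FD ~ 0.1 mm) is synthesised per subject.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: a list with `subjects` (each
#'   with `subject_id`, `group`, `age`, `sex`, `tc` (a [time_course_matrix()]),
#'   `motion` (a [motion_trace()])) and `truth` (timepoint-level state labels,
#'   planted covariances and transition matrices, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  p <- cfg$n_components
  Tn <- cfg$n_timepoints
  chols <- lapply(cfg$state_covariances, chol)
  comp_ids <- sprintf("C%02d", seq_len(p))
  groups <- names(cfg$group_transition_matrices)
  if (is.null(groups)) groups <- c("control", "patient")
  subjects <- list()
  truth_labels <- list()
  idx <- 0
  for (g in 1:2) {
    P <- cfg$group_transition_matrices[[g]]
    bad <- seq_len(cfg$n_subjects_per_group) <= cfg$n_bad_subjects_per_group
    for (s in seq_len(cfg$n_subjects_per_group)) {
      idx <- idx + 1
      sid <- sprintf("sub-%03d", idx)
      labs <- sample_state_sequence(P, Tn)
      Z <- matrix(stats::rnorm(Tn * p), Tn, p)
      X <- matrix(0, Tn, p)
      for (st in seq_along(chols)) {
        sel <- labs == st
        if (any(sel)) X[sel, ] <- Z[sel, , drop = FALSE] %*% chols[[st]]
      }
      if (cfg$observation_noise_sd > 0)
        X <- X + matrix(stats::rnorm(Tn * p, sd = cfg$observation_noise_sd), Tn, p)
      if (cfg$drift_amplitude > 0) {
        tt <- seq_len(Tn) * cfg$tr_seconds
        lin <- seq(-0.5, 0.5, length.out = Tn)
        for (j in seq_len(p)) {
          phase <- stats::runif(1, 0, 2 * pi)
          slope <- sample(c(-1, 1), 1)
          X[, j] <- X[, j] + cfg$drift_amplitude *
            (slope * lin + sin(2 * pi * 0.005 * tt + phase))
        }
      }
      if (cfg$spike_rate > 0) {
        amp <- 6 * max(cfg$observation_noise_sd, 0.1)
        hit <- matrix(stats::runif(Tn * p) < cfg$spike_rate, Tn, p)
        X[hit] <- X[hit] + amp * sample(c(-1, 1), sum(hit), replace = TRUE)
      }
      motion <- simulate_motion_trace(Tn, target_mean_fd = if (bad[s]) 0.30 else 0.10)
      age <- stats::rnorm(1, cfg$covariate_spec$age_mean[g], cfg$covariate_spec$age_sd[g])
      sex <- as.integer(stats::runif(1) < cfg$covariate_spec$sex_prop[g])
      subjects[[idx]] <- list(
        subject_id = sid, group = groups[g], age = round(age, 1), sex = sex,
        tc = time_course_matrix(X, cfg$tr_seconds, sid, comp_ids),
        motion = motion
      )
      truth_labels[[sid]] <- labs
    }
  }
  structure(list(
    subjects = subjects,
    truth = list(labels = truth_labels,
                 state_covariances = cfg$state_covariances,
                 group_transition_matrices = cfg$group_transition_matrices,
                 seed = cfg$seed)
  ), class = "synthetic_cohort")
}

# Smoothed mean-reverting (AR(1)) rigid-body motion, rescaled so the
# Jenkinson mean FD hits target_mean_fd (FD is ~linear in the parameters at
# this scale). Mean reversion keeps absolute positions realistically bounded
# rather than drifting like a free random walk.
simulate_motion_trace <- function(n_timepoints, target_mean_fd = 0.10) {
  smooth_walk <- function(sd) {
    e <- stats::rnorm(n_timepoints, sd = sd)
    x <- as.numeric(stats::filter(e, 0.8, method = "recursive"))
    stats::filter(c(rep(x[1], 4), x, rep(x[n_timepoints], 4)),
                  rep(1 / 9, 9), sides = 2)[5:(n_timepoints + 4)]
  }
  trans <- sapply(1:3, function(i) smooth_walk(0.05))
  rot <- sapply(1:3, function(i) smooth_walk(0.0005))
  m <- motion_trace(trans, rot)
  fd <- framewise_displacement(m)
  mfd <- mean(fd)
  if (mfd > 0) {
    sc <- target_mean_fd / mfd
    m <- motion_trace(trans * sc, rot * sc)
  }
  m
}

#' Write a synthetic cohort to disk
#'
#' Emits one time-course TSV and one 6-column motion TSV per subject, a
#' manifest CSV (`subject_id`, `group`, `age`, `sex`, `tc_path`,
#' `motion_path`) and a ground-truth JSON (state labels, planted matrices,
#' seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    tc_path <- file.path(dir, paste0(s$subject_id, "_timecourses.tsv"))
    mo_path <- file.path(dir, paste0(s$subject_id, "_motion.tsv"))
    write_timecourse_tsv(s$tc, tc_path)
    write_motion_tsv(s$motion, mo_path)
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, tc_path = basename(tc_path),
               motion_path = basename(mo_path), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(labels = truth$labels,
         state_covariances = lapply(truth$state_covariances, unclass),
         group_transition_matrices = lapply(truth$group_transition_matrices, unclass),
         seed = truth$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(manifest)
}
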