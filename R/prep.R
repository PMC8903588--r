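#' Component time-course matrix
#'
#' @param values numeric matrix, timepoints x components, no missing values.
#' @param tr_seconds sampling interval (s).
#' @param subject_id subject identifier.
#' @param component_ids optional component labels (default `C01`, `C02`, ...).
#' @return object of class `time_course_matrix`.
#' @export
time_course_matrix <- function(values, tr_seconds, subject_id = "sub-001",
                               component_ids = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), all(is.finite(values)), tr_seconds > 0)
  if (is.null(component_ids)) component_ids <- sprintf("C%02d", seq_len(ncol(values)))
  stopifnot(length(component_ids) == ncol(values))
  dimnames(values) <- list(NULL, component_ids)
  structure(list(values = values, tr_seconds = tr_seconds,
                 subject_id = subject_id, component_ids = component_ids),
            class = "time_course_matrix")
}

#' Rigid-body head-motion trace
#'
#' @param translations_mm numeric matrix, timepoints x 3 (mm).
#' @param rotations_rad numeric matrix, timepoints x 3 (radians).
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations_mm, rotations_rad) {
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  stopifnot(ncol(translations_mm) == 3, ncol(rotations_rad) == 3,
            nrow(translations_mm) == nrow(rotations_rad),
            all(is.finite(translations_mm)), all(is.finite(rotations_rad)))
  structure(list(translations_mm = translations_mm,
                 rotations_rad = rotations_rad),
            class = "motion_trace")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints of a time-course matrix (and of a
#' motion trace if supplied), mirroring the usual discarding of pre-steady-state
#' volumes: e.g. a 180-volume acquisition minus the first 10 leaves 170.
#'
#' @param tc a [time_course_matrix()].
#' @param n_discard number of leading timepoints to drop (default 10).
#' @param motion optional [motion_trace()] trimmed in step.
#' @return the trimmed `time_course_matrix`, or a list with `tc` and `motion`
#'   when `motion` is supplied.
#' @export
discard_initial_volumes <- function(tc, n_discard = 10, motion = NULL) {
  stopifnot(inherits(tc, "time_course_matrix"),
            n_discard >= 0, n_discard < nrow(tc$values))
  keep <- seq.int(n_discard + 1, nrow(tc$values))
  out <- time_course_matrix(tc$values[keep, , drop = FALSE], tc$tr_seconds,
                            tc$subject_id, tc$component_ids)
  if (is.null(motion)) return(out)
  list(tc = out,
       motion = motion_trace(motion$translations_mm[keep, , drop = FALSE],
                             motion$rotations_rad[keep, , drop = FALSE]))
}

# Rigid-body transform from 6 parameters: rotations Rx Ry Rz applied in that
# order, then translation. 4x4 homogeneous matrix.
rigid_transform <- function(trans, rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  M <- diag(4)
  M[1:3, 1:3] <- Rx %*% Ry %*% Rz
  M[1:3, 4] <- trans
  M
}

#' Jenkinson framewise displacement
#'
#' RMS deviation between consecutive rigid-body transforms, averaged over a
#' sphere of radius `sphere_radius_mm` centred at the origin:
#' `FD_t = sqrt(R^2/5 * tr(A'A) + b'b)` where `[A b] = T_t T_{t-1}^{-1} - I`.
#' A pure translation step of d mm gives FD = d; a small rotation step of
#' theta rad about one axis gives FD ~ R * theta * sqrt(2/5).
#'
#' @param motion a [motion_trace()].
#' @param sphere_radius_mm sphere radius (default 80 mm).
#' @return numeric FD series, one value per timepoint, first element 0.
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 80) {
  stopifnot(inherits(motion, "motion_trace"))
  n <- nrow(motion$translations_mm)
  if (n < 2) stop("framewise displacement needs at least 2 timepoints")
  Ts <- lapply(seq_len(n), function(t)
    rigid_transform(motion$translations_mm[t, ], motion$rotations_rad[t, ]))
  fd <- numeric(n)
  for (t in 2:n) {
    M <- Ts[[t]] %*% solve(Ts[[t - 1]]) - diag(4)
    A <- M[1:3, 1:3]
    b <- M[1:3, 4]
    fd[t] <- sqrt(sphere_radius_mm^2 / 5 * sum(A * A) + sum(b * b))
  }
  fd
}

#' Motion quality-control report
#'
#' A subject is excluded when mean FD exceeds `mean_fd`, any absolute
#' translation exceeds `max_translation` (mm), or any absolute rotation
#' exceeds `max_rotation` (degrees) - strict inequalities, so a subject
#' sitting exactly at a threshold is retained.
#'
#' @param fd FD series from [framewise_displacement()].
#' @param motion the subject's [motion_trace()].
#' @param thresholds list with `mean_fd` (mm, default 0.2), `max_translation`
#'   (mm, default 1.5), `max_rotation` (degrees, default 1.5).
#' @return list of class `qc_report`: `mean_fd_mm`, `max_translation_mm`,
#'   `max_rotation_deg`, `excluded`, `reasons`.
#' @export
qc_exclude <- function(fd, motion,
                       thresholds = list(mean_fd = 0.2, max_translation = 1.5,
                                         max_rotation = 1.5)) {
  stopifnot(inherits(motion, "motion_trace"), length(fd) == nrow(motion$translations_mm))
  mean_fd <- mean(fd)
  max_trans <- max(abs(motion$translations_mm))
  max_rot_deg <- max(abs(motion$rotations_rad)) * 180 / pi
  reasons <- character(0)
  if (mean_fd > thresholds$mean_fd) reasons <- c(reasons, "mean_fd")
  if (max_trans > thresholds$max_translation) reasons <- c(reasons, "max_translation")
  if (max_rot_deg > thresholds$max_rotation) reasons <- c(reasons, "max_rotation")
  structure(list(mean_fd_mm = mean_fd, max_translation_mm = max_trans,
                 max_rotation_deg = max_rot_deg,
                 excluded = length(reasons) > 0, reasons = reasons),
            class = "qc_report")
}

#' Polynomial detrending
#'
#' Removes, per component, the least-squares polynomial of the given order
#' (0 = mean, 1 = mean + linear trend, 2 = quadratic).
#'
#' @param tc a [time_course_matrix()].
#' @param order polynomial order in 0..2 (default 1).
#' @return detrended `time_course_matrix`.
#' @export
detrend_timecourses <- function(tc, order = 1) {
  stopifnot(inherits(tc, "time_course_matrix"), order %in% 0:2)
  n <- nrow(tc$values)
  if (order >= n) stop("polynomial order must be below the number of timepoints")
  t01 <- seq(0, 1, length.out = n)
  X <- matrix(1, n, 1)
  if (order > 0)
    X <- cbind(X, stats::poly(t01, degree = order, raw = TRUE))
  res <- as.matrix(stats::lm.fit(X, tc$values)$residuals)
  time_course_matrix(res, tc$tr_seconds, tc$subject_id, tc$component_ids)
}

# Low-order Fourier baseline used by the despiker: intercept + linear trend +
# floor(n/30)+1 sine/cosine pairs over the series duration.
despike_basis <- function(n) {
  t01 <- seq(0, 1, length.out = n)
  k <- floor(n / 30) + 1
  X <- cbind(1, t01)
  for (j in seq_len(k))
    X <- cbind(X, sin(2 * pi * j * t01), cos(2 * pi * j * t01))
  X
}

#' Despike time courses
#'
#' Per component: fit a smooth low-order Fourier baseline, scale the residuals
#' by a robust SD (MAD x 1.4826), leave residuals within `c1` robust SDs
#' untouched, and compress larger ones to
#' `sign(s) * (c1 + (c2-c1) * tanh((|s|-c1)/(c2-c1)))` robust SDs, so no value
#' ends further than `c2` robust SDs from the baseline.
#'
#' @param tc a [time_course_matrix()].
#' @param c1 lower clip in robust SDs (default 2.5).
#' @param c2 asymptotic cap in robust SDs (default 4).
#' @return despiked `time_course_matrix`. Components with zero MAD (flat
#'   residuals) are returned unchanged.
#' @export
despike_timecourses <- function(tc, c1 = 2.5, c2 = 4) {
  stopifnot(inherits(tc, "time_course_matrix"), c1 > 0, c2 > c1)
  X <- despike_basis(nrow(tc$values))
  resid_mat <- as.matrix(stats::lm.fit(X, tc$values)$residuals)
  base <- tc$values - resid_mat
  out <- tc$values
  for (j in seq_len(ncol(out))) {
    r <- resid_mat[, j]
    sc <- stats::mad(r)
    if (sc == 0) next
    s <- r / sc
    big <- abs(s) > c1
    s[big] <- sign(s[big]) * (c1 + (c2 - c1) * tanh((abs(s[big]) - c1) / (c2 - c1)))
    out[, j] <- base[, j] + s * sc
  }
  time_course_matrix(out, tc$tr_seconds, tc$subject_id, tc$component_ids)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a fifth-order Butterworth low-pass forward and backward
#' (zero-phase; the effective power response is the square of the single-pass
#' response), per component. DC gain is 1.
#'
#' @param tc a [time_course_matrix()].
#' @param cutoff_hz cutoff frequency (default 0.15 Hz); must be below the
#'   Nyquist frequency `1/(2*tr_seconds)`.
#' @param order filter order (default 5).
#' @return filtered `time_course_matrix`.
#' @export
lowpass_timecourses <- function(tc, cutoff_hz = 0.15, order = 5) {
  stopifnot(inherits(tc, "time_course_matrix"), cutoff_hz > 0)
  nyq <- 1 / (2 * tc$tr_seconds)
  if (cutoff_hz >= nyq) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  n <- nrow(tc$values)
  pad <- min(n - 1, 100)  # even-reflection padding tames filter edge effects
  out <- apply(tc$values, 2, function(x) {
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    yp <- signal::filtfilt(bf, xp)
    yp[(pad + 1):(pad + n)]
  })
  time_course_matrix(out, tc$tr_seconds, tc$subject_id, tc$component_ids)
}

#' Regress nuisance signals out of time courses
#'
#' Ordinary least-squares residualisation of each component against an
#' intercept plus the supplied regressors (typically the 6 motion parameters).
#'
#' @param tc a [time_course_matrix()].
#' @param regressors numeric matrix, timepoints x p, full column rank
#'   after adding the intercept.
#' @return residual `time_course_matrix` (demeaned, orthogonal to every
#'   regressor).
#' @export
regress_nuisance <- function(tc, regressors) {
  stopifnot(inherits(tc, "time_course_matrix"))
  regressors <- as.matrix(regressors)
  stopifnot(nrow(regressors) == nrow(tc$values))
  X <- cbind(intercept = 1, regressors)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])
    lab <- colnames(X)[bad]
    if (is.null(lab)) lab <- paste0("column ", bad)
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(lab, collapse = ", "))
  }
  res <- as.matrix(stats::lm.fit(X, tc$values)$residuals)
  time_course_matrix(res, tc$tr_seconds, tc$subject_id, tc$component_ids)
}

#' Low-frequency power ratio of a component time course
#'
#' Ratio of integrated raw-periodogram power below 0.1 Hz to power in the
#' 0.15-0.25 Hz band. Components dominated by low-frequency fluctuations have
#' a large ratio; this is the spectral criterion used to keep meaningful
#' components.
#'
#' @param x numeric series (length >= 32).
#' @param tr_seconds sampling interval (s).
#' @return list with `ratio` and logical `undefined` (TRUE when the
#'   denominator band holds essentially zero power; `ratio` is then computed
#'   against a machine-epsilon floor).
#' @export
low_freq_power_ratio <- function(x, tr_seconds) {
  stopifnot(length(x) >= 32, tr_seconds > 0)
  n <- length(x)
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) / (n * tr_seconds)
  half <- seq(2, floor(n / 2) + 1)
  pw <- pw[half]; freq <- freq[half]
  num <- sum(pw[freq > 0 & freq <= 0.1])
  den <- sum(pw[freq >= 0.15 & freq <= 0.25])
  undefined <- den <= .Machine$double.eps * sum(pw)
  list(ratio = num / max(den, .Machine$double.eps * max(sum(pw), 1)),
       undefined = undefined)
}

#' Full time-course post-processing pipeline
#'
#' Fixed stage order: detrend, despike, low-pass filter, motion-parameter
#' regression (the last only when a motion trace is supplied).
#'
#' @param tc a [time_course_matrix()].
#' @param motion optional [motion_trace()] whose 6 parameters are regressed
#'   out at the final stage.
#' @param detrend_order,despike_c1,despike_c2,cutoff_hz,filter_order stage
#'   parameters, see the individual stage functions.
#' @return cleaned `time_course_matrix`.
#' @export
preprocess_timecourses <- function(tc, motion = NULL, detrend_order = 1,
                                   despike_c1 = 2.5, despike_c2 = 4,
                                   cutoff_hz = 0.15, filter_order = 5) {
  out <- detrend_timecourses(tc, detrend_order)
  out <- despike_timecourses(out, despike_c1, despike_c2)
  out <- lowpass_timecourses(out, cutoff_hz, filter_order)
  if (!is.null(motion))
    out <- regress_nuisance(out, cbind(motion$translations_mm, motion$rotations_rad))
  out
}
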