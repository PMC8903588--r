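#' Covariate-adjusted two-group permutation test
#'
#' The metric is first residualised against an intercept plus the covariates;
#' the observed statistic is the difference of group means of these residuals
#' (first group minus second, groups in order of first appearance). The null
#' distribution is built by permuting the group labels `n_perm` times, and the
#' two-sided p-value is `(1 + #(|T_perm| >= |T_obs|)) / (1 + n_perm)`, so it
#' is never below `1/(n_perm + 1)`.
#'
#' Subjects with undefined (`NA`) values are dropped (count reported).
#'
#' @param values per-subject metric values.
#' @param groups two-level group label per subject.
#' @param covariates optional data frame / matrix of per-subject covariates
#'   (e.g. age, sex).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return object of class `group_test`: `observed_stat`, `p`, `n_perm`,
#'   `n_dropped`, `group_summaries` (mean and SD of the raw values per
#'   group), `seed`.
#' @export
permutation_test <- function(values, groups, covariates = NULL,
                             n_perm = 10000, seed = 1L) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(covariates) == length(values))
    ok <- ok & stats::complete.cases(covariates)
  }
  n_dropped <- sum(!ok)
  values <- values[ok]
  groups <- groups[ok]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs at least 2 subjects")
  res <- if (is.null(covariates)) {
    values - mean(values)
  } else {
    stats::lm.fit(cbind(1, covariates[ok, , drop = FALSE]), values)$residuals
  }
  g1 <- groups == lev[1]
  stat_of <- function(sel) mean(res[sel]) - mean(res[!sel])
  obs <- stat_of(g1)
  n <- length(res)
  n1 <- sum(g1)
  exceed <- withr::with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      perm <- logical(n)
      perm[sample.int(n, n1)] <- TRUE
      if (abs(stat_of(perm)) >= abs(obs)) cnt <- cnt + 1L
    }
    cnt
  })
  summaries <- vapply(lev, function(l)
    c(mean = mean(values[groups == l]), sd = stats::sd(values[groups == l])),
    numeric(2))
  structure(list(observed_stat = obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, n_dropped = n_dropped,
                 group_summaries = summaries, seed = seed),
            class = "group_test")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p-values (via `stats::p.adjust`,
#' method `"BH"`) plus the rejection set at level `q`: the largest rank i
#' with `p_(i) <= i q / m` and all smaller ranks are rejected.
#'
#' @param p_values p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`, in input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Spearman partial correlation
#'
#' Ranks x, y and every covariate (average ranks for ties), residualises the
#' ranked x and y on the ranked covariates plus an intercept, and correlates
#' the residuals (Pearson); with no covariates this equals the plain Spearman
#' rho. The p-value comes from `t = rho * sqrt((n - 2 - k)/(1 - rho^2))` on
#' `n - 2 - k` degrees of freedom, k the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame / matrix of covariates to partial
#'   out (e.g. age, sex, education, mean FD).
#' @return object of class `partial_corr`: `rho`, `p`, `n`, `df`,
#'   `covariates_used`. `rho` is `NA` (undefined) when x or y is constant
#'   after ranking.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(cv) == length(x))
    keep <- keep & stats::complete.cases(cv)
    cv <- cv[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(cv)) 0L else ncol(cv)
  if (n <= k + 2) stop("need n > #covariates + 2 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n, df = n - 2L - k,
                          covariates_used = colnames(cv)),
                     class = "partial_corr"))
  if (k > 0) {
    rc <- apply(cv, 2, rank)
    X <- cbind(1, rc)
    if (qr(X)$rank < ncol(X)) stop("covariates collinear after ranking")
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
    if (stats::sd(rx) == 0)
      stop("x is collinear with the covariates after ranking")
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(rho = rho, p = p, n = n, df = df,
                 covariates_used = colnames(cv)),
            class = "partial_corr")
}

#' Run a family-structured battery of group comparisons
#'
#' Applies [permutation_test()] to every metric column and
#' Benjamini-Hochberg correction within each declared family (e.g. the
#' fractional-windows family, the dwell-time family, the nodal-CV family);
#' metrics outside any family keep their uncorrected p.
#'
#' @param metrics data frame with `subject_id` plus one column per metric.
#' @param manifest data frame with `subject_id`, `group` and any covariate
#'   columns named in `covariate_cols`.
#' @param families named list of character vectors of metric columns; each
#'   vector is one FDR family.
#' @param covariate_cols covariate column names in `manifest` (default
#'   `c("age", "sex")`).
#' @param n_perm,seed forwarded to [permutation_test()].
#' @param q FDR level (default 0.05).
#' @return data frame: metric, family, group means/SDs, observed statistic,
#'   p, p_fdr, significant.
#' @export
compare_all <- function(metrics, manifest, families = list(),
                        covariate_cols = c("age", "sex"),
                        n_perm = 10000, seed = 1L, q = 0.05) {
  stopifnot("subject_id" %in% names(metrics), "subject_id" %in% names(manifest),
            "group" %in% names(manifest))
  extra <- setdiff(metrics$subject_id, manifest$subject_id)
  if (length(extra) > 0)
    stop("subjects missing from manifest: ", paste(extra, collapse = ", "))
  manifest <- manifest[match(metrics$subject_id, manifest$subject_id), ]
  covs <- if (length(covariate_cols) > 0)
    manifest[, covariate_cols, drop = FALSE] else NULL
  cols <- setdiff(names(metrics), "subject_id")
  lev <- unique(as.character(manifest$group))
  rows <- lapply(seq_along(cols), function(i) {
    gt <- permutation_test(metrics[[cols[i]]], manifest$group, covs,
                           n_perm = n_perm, seed = seed + i)
    data.frame(metric = cols[i],
               mean_1 = gt$group_summaries["mean", lev[1]],
               sd_1 = gt$group_summaries["sd", lev[1]],
               mean_2 = gt$group_summaries["mean", lev[2]],
               sd_2 = gt$group_summaries["sd", lev[2]],
               stat = gt$observed_stat, p = gt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$family <- NA_character_
  out$p_fdr <- out$p
  for (fam in names(families)) {
    sel <- out$metric %in% families[[fam]]
    if (!any(sel)) next
    out$family[sel] <- fam
    out$p_fdr[sel] <- fdr_bh(out$p[sel], q)$p_adjusted
  }
  out$significant <- out$p_fdr <= q
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "sd_1"] <- paste0("sd_", lev[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lev[2])
  names(out)[names(out) == "sd_2"] <- paste0("sd_", lev[2])
  out
}
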