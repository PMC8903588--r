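#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the
#' standard defaults: 20-TR window in steps of 1 TR with a rectangle-
#' convolved-Gaussian taper (sigma 3), graphical-lasso penalty 0.1 (or
#' `"auto"` for cross-validated selection), silhouette-based k selection over
#' 2..8 with 100 k-medians restarts, sparsity grid 0.10-0.35 by 0.01, 100
#' random reference graphs, 10,000 permutations, SD/mean CV. All stage seeds
#' are derived deterministically from the single master `seed`.
#'
#' @param tr_seconds TR in seconds.
#' @param window_len,step,taper_sigma windowing parameters.
#' @param lasso_penalty numeric penalty, or `"auto"`.
#' @param lambda_grid candidate grid used when `lasso_penalty = "auto"`.
#' @param lambda_repetitions train/test splits for `"auto"` selection.
#' @param k number of states, or `"auto"` for silhouette selection.
#' @param k_range candidate k values for `"auto"`.
#' @param n_init k-medians restarts.
#' @param sparsity_from,sparsity_to,sparsity_by threshold grid.
#' @param n_random random reference graphs per window/threshold.
#' @param cv_definition `"sd_over_mean"` or `"mean_over_sd"`.
#' @param n_perm permutations for group tests.
#' @param modularity_runs,modularity_tau consensus-clustering parameters.
#' @param fd_thresh,trans_thresh,rot_thresh QC exclusion thresholds
#'   (mm, mm, degrees).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(tr_seconds = 2, window_len = 20, step = 1,
                       taper_sigma = 3, lasso_penalty = 0.1,
                       lambda_grid = c(0.03, 0.1, 0.3), lambda_repetitions = 10,
                       k = "auto", k_range = 2:8, n_init = 100,
                       sparsity_from = 0.10, sparsity_to = 0.35,
                       sparsity_by = 0.01, n_random = 100,
                       cv_definition = "sd_over_mean", n_perm = 10000,
                       modularity_runs = 100, modularity_tau = 0.5,
                       fd_thresh = 0.2, trans_thresh = 1.5, rot_thresh = 1.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

# deterministic per-stage seeds below 2^31
derive_seed <- function(master, stage) {
  offsets <- c(prep = 1L, dfnc = 2L, states = 3L, modularity = 4L,
               topology = 5L, stats = 6L)
  (as.integer(master) %% 2000000L) * 1000L + offsets[[stage]]
}

#' Run the full dynamic-connectivity pipeline
#'
#' Executes prep (QC + time-course cleaning), dFNC (tapered windows +
#' graphical lasso + Fisher z + age/sex residualisation), state clustering
#' with temporal metrics, state-centroid modularity, dynamic topology, and
#' group statistics, writing every artifact plus a JSON run manifest (with
#' md5 content hashes and all parameters used) into `out_dir`. Re-running
#' with the same inputs and configuration reproduces identical hashes.
#'
#' @param input_dir directory holding `manifest.csv` and the per-subject
#'   TSVs (the layout written by [write_cohort()]).
#' @param out_dir output directory (created).
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the path
#'   of the run manifest.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(file.path(input_dir, "manifest.csv"))

  ## prep: QC + cleaning
  qc_rows <- list()
  cleaned <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    tc <- read_timecourse_tsv(manifest$tc_path[i], config$tr_seconds, sid)
    motion <- read_motion_tsv(manifest$motion_path[i])
    if (nrow(motion$translations_mm) != nrow(tc$values))
      stop(sprintf("stage prep, subject %s: motion rows != timepoints", sid))
    fd <- framewise_displacement(motion)
    qc <- qc_exclude(fd, motion, list(mean_fd = config$fd_thresh,
                                      max_translation = config$trans_thresh,
                                      max_rotation = config$rot_thresh))
    qc_rows[[i]] <- data.frame(subject_id = sid, mean_fd_mm = qc$mean_fd_mm,
                               max_translation_mm = qc$max_translation_mm,
                               max_rotation_deg = qc$max_rotation_deg,
                               excluded = qc$excluded,
                               reasons = paste(qc$reasons, collapse = ";"))
    if (!qc$excluded)
      cleaned[[sid]] <- preprocess_timecourses(tc, motion)
  }
  qc_table <- do.call(rbind, qc_rows)
  utils::write.csv(qc_table, file.path(out_dir, "qc.csv"), row.names = FALSE)
  manifest <- manifest[!qc_table$excluded, ]
  if (nrow(manifest) < 4) stop("stage prep: fewer than 4 subjects survive QC")

  ## dfnc
  taper <- build_taper(config$window_len, config$taper_sigma)
  lam <- config$lasso_penalty
  if (identical(lam, "auto")) {
    lam <- select_lasso_penalty(cleaned[[1]], taper, config$lambda_grid,
                                n_repetitions = config$lambda_repetitions,
                                step = config$step,
                                seed = derive_seed(config$seed, "dfnc"))$lambda
  }
  series <- lapply(cleaned, function(tc)
    windowed_fc(tc, taper, step = config$step, lasso_penalty = lam))
  series <- residualize_connectivity(series, manifest)
  for (s in series)
    write_edge_table(s, file.path(out_dir, paste0(s$subject_id, "_edges.tsv")))

  ## states
  pooled <- pool_windows(series)
  if (identical(config$k, "auto")) {
    sel <- select_k(pooled$X, k_range = config$k_range, n_init = config$n_init,
                    seed = derive_seed(config$seed, "states"),
                    subject = pooled$subject)
    model <- sel$model
    utils::write.csv(data.frame(k = as.integer(names(sel$silhouette_by_k)),
                                silhouette = sel$silhouette_by_k),
                     file.path(out_dir, "silhouette.csv"), row.names = FALSE)
  } else {
    model <- cluster_windows(pooled$X, config$k, n_init = config$n_init,
                             seed = derive_seed(config$seed, "states"),
                             subject = pooled$subject)
  }
  utils::write.table(
    data.frame(subject = pooled$subject, window = pooled$window,
               state = model$labels),
    file.path(out_dir, "state_labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(cbind(state = seq_len(model$k), model$centroids),
                     file.path(out_dir, "state_centroids.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tm <- lapply(model$labels_by_subject, temporal_metrics, k = model$k)
  tm_df <- do.call(rbind, lapply(names(tm), function(sid) {
    m <- tm[[sid]]
    row <- data.frame(subject_id = sid,
                      t(m$fractional_windows), t(m$mean_dwell),
                      n_transitions = m$n_transitions)
    names(row) <- c("subject_id",
                    paste0("frac_state", seq_len(model$k)),
                    paste0("dwell_state", seq_len(model$k)),
                    "n_transitions")
    row
  }))
  utils::write.csv(tm_df, file.path(out_dir, "temporal_metrics.csv"),
                   row.names = FALSE)

  ## modularity
  n_comp <- length(series[[1]]$component_ids)
  parts <- state_modularity(model, n_comp, n_runs = config$modularity_runs,
                            tau = config$modularity_tau,
                            seed = derive_seed(config$seed, "modularity"))
  jsonlite::write_json(
    lapply(parts, function(p) list(q = p$q_value, n_modules = p$n_modules,
                                   module_of = p$module_of)),
    file.path(out_dir, "modularity.json"), digits = NA, auto_unbox = TRUE)

  ## topology
  profile <- threshold_profile(config$sparsity_from, config$sparsity_to,
                               config$sparsity_by)
  topo <- lapply(series, function(s)
    dynamic_topology(s, profile, n_random = config$n_random,
                     seed = derive_seed(config$seed, "topology"),
                     cv_definition = config$cv_definition))
  cv_df <- do.call(rbind, lapply(topo, function(tp)
    data.frame(subject_id = tp$subject_id, t(tp$cv))))
  utils::write.csv(cv_df, file.path(out_dir, "topology_cv.csv"),
                   row.names = FALSE)
  nodal_df <- do.call(rbind, lapply(topo, function(tp) {
    row <- data.frame(subject_id = tp$subject_id, t(tp$nodal_cv))
    names(row) <- c("subject_id", paste0("node_cv_", series[[1]]$component_ids))
    row
  }))
  utils::write.csv(nodal_df, file.path(out_dir, "topology_nodal_cv.csv"),
                   row.names = FALSE)

  ## stats
  metrics <- merge(tm_df, cv_df, by = "subject_id")
  metrics <- merge(metrics, nodal_df, by = "subject_id")
  families <- list(
    fractional_windows = grep("^frac_", names(metrics), value = TRUE),
    dwell_time = grep("^dwell_", names(metrics), value = TRUE),
    nodal_cv = grep("^node_cv_", names(metrics), value = TRUE)
  )
  results <- compare_all(metrics, manifest, families,
                         covariate_cols = c("age", "sex"),
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "stats"))
  utils::write.csv(results, file.path(out_dir, "group_results.csv"),
                   row.names = FALSE)

  ## run manifest with content hashes
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "run_manifest.json"]
  run_manifest <- list(
    parameters = c(unclass(config),
                   list(lasso_penalty_used = lam, k_used = model$k,
                        n_windows = length(series[[1]]$window_starts),
                        n_subjects = nrow(manifest))),
    artifacts = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(list(qc = qc_table, series = series, model = model,
                 temporal_metrics = tm_df, modularity = parts,
                 topology = topo, results = results,
                 run_manifest = manifest_path))
}
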