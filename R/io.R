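#' Write / read a time-course TSV
#'
#' Tab-separated, header row of component ids, one row per timepoint, '.'
#' decimal, UTF-8. The TR is not stored in the file; it is supplied on read
#' (it lives in the cohort manifest / run configuration).
#'
#' @param tc a [time_course_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "time_course_matrix"))
  utils::write.table(tc$values, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_tsv
#' @param tr_seconds sampling interval of the stored series.
#' @param subject_id subject identifier to attach.
#' @export
read_timecourse_tsv <- function(path, tr_seconds, subject_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, TRUE))
    stop(sprintf("%s: non-numeric values in column(s) %s", path,
                 paste(names(df)[bad], collapse = ", ")))
  }
  if (anyNA(m)) {
    row <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("%s: missing value at data line %d", path, row))
  }
  if (is.null(subject_id))
    subject_id <- sub("_timecourses\\.tsv$", "", basename(path))
  time_course_matrix(m, tr_seconds, subject_id, colnames(m))
}

#' Write / read a 6-parameter motion TSV
#'
#' Columns `trans_x trans_y trans_z` (mm) and `rot_x rot_y rot_z` (radians).
#'
#' @param motion a [motion_trace()].
#' @param path file path.
#' @return invisibly `path` (write) / a `motion_trace` (read).
#' @export
write_motion_tsv <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  df <- cbind(motion$translations_mm, motion$rotations_rad)
  colnames(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  motion_trace(as.matrix(df[, need[1:3]]), as.matrix(df[, need[4:6]]))
}

#' Read a cohort manifest CSV
#'
#' Requires columns `subject_id`, `group`, `age`, `sex`, `tc_path`,
#' `motion_path`; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest CSV path.
#' @return data frame with absolute `tc_path` / `motion_path`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "tc_path", "motion_path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  base <- dirname(normalizePath(path))
  for (col in c("tc_path", "motion_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}

#' Write a per-subject window edge table
#'
#' Rows = windows, columns = upper-triangle edges labelled `Ci_Cj` (the
#' [mat_to_edges()] ordering), plus a JSON sidecar of windowing parameters.
#'
#' @param series a [windowed_fc()] result.
#' @param path output TSV path (sidecar gets extension `.json`).
#' @return invisibly, `path`.
#' @export
write_edge_table <- function(series, path) {
  stopifnot(inherits(series, "window_series"))
  X <- window_edge_matrix(series)
  utils::write.table(X, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(list(subject_id = series$subject_id,
           window_starts = series$window_starts), series$params),
    sub("\\.tsv$", ".json", path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
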