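#' Hierarchical sample table
#'
#' The central data container: an `N x D` feature matrix together with the
#' hierarchical annotations that drive every splitting scheme -- subject,
#' session, optional trial, and a within-(subject, session) time index.
#' Rows are instances (e.g. one epoched window of derived neural features);
#' subjects contain sessions, sessions optionally contain trials, and the
#' time index gives a strict temporal order inside each (subject, session).
#'
#' Labels are stored as a factor so the code-to-name mapping is retained for
#' reports. `time_index` is 0-based and must be strictly increasing within
#' each (subject, session); duplicate timestamps are rejected rather than
#' tie-broken, because time-blocked splits need a total order.
#'
#' @param features numeric matrix (`N x D`, `D >= 1`) of derived features.
#' @param labels length-`N` vector (factor, character, or numeric codes) of
#'   class labels or binary targets.
#' @param subject_id length-`N` subject identifiers; no missing values.
#' @param session_id length-`N` session identifiers nested in subject; no
#'   missing values.
#' @param trial_id optional length-`N` trial identifiers nested in session,
#'   or `NULL` when the design has no trial structure.
#' @param time_index length-`N` non-negative integers, strictly increasing
#'   within each (subject, session).
#' @return An object of class `sample_table`: a list with elements
#'   `features`, `labels`, `subject_id`, `session_id`, `trial_id`,
#'   `time_index`.
#' @examples
#' tab <- sample_table(matrix(rnorm(12), 4, 3),
#'                     labels = c("a", "b", "a", "b"),
#'                     subject_id = c("s1", "s1", "s2", "s2"),
#'                     session_id = rep("e1", 4),
#'                     time_index = c(0, 1, 0, 1))
#' summary(tab)
#' @export
sample_table <- function(features, labels, subject_id, session_id,
                         trial_id = NULL, time_index) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  assert_that(ncol(features) >= 1, "features must have D >= 1 columns")
  if (!is.factor(labels)) labels <- factor(labels)
  tab <- structure(
    list(features   = features,
         labels     = labels,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         trial_id   = if (is.null(trial_id)) NULL else as.character(trial_id),
         time_index = as.integer(time_index)),
    class = "sample_table")
  validate_sample_table(tab)
  tab
}

#' Validate a sample table's structural invariants
#'
#' Checks equal row lengths, non-missing subject/session identifiers, and
#' strictly increasing `time_index` within each (subject, session),
#' reporting the first offending row on violation.
#'
#' @param tab a [sample_table].
#' @return `tab`, invisibly, if valid; otherwise an error.
#' @export
validate_sample_table <- function(tab) {
  n <- nrow(tab$features)
  for (fld in c("labels", "subject_id", "session_id", "time_index")) {
    assert_that(length(tab[[fld]]) == n,
                "length of ", fld, " (", length(tab[[fld]]),
                ") does not match number of feature rows (", n, ")")
  }
  if (!is.null(tab$trial_id))
    assert_that(length(tab$trial_id) == n,
                "length of trial_id does not match number of feature rows")
  assert_that(!anyNA(tab$subject_id) && !any(tab$subject_id == ""),
              "every row must have a non-missing subject_id")
  assert_that(!anyNA(tab$session_id) && !any(tab$session_id == ""),
              "every row must have a non-missing session_id")
  assert_that(!anyNA(tab$time_index) && all(tab$time_index >= 0L),
              "time_index must be non-negative integers")
  grp <- paste(tab$subject_id, tab$session_id, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ti <- tab$time_index[idx]
    bad <- which(diff(ti) <= 0)
    if (length(bad))
      fail("time_index not strictly increasing within (subject, session) (",
           sub("\r", ", ", g), "): first offending row ", idx[bad[1] + 1])
  }
  invisible(tab)
}

#' @export
print.sample_table <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<sample_table> N=%d instances, M=%d subjects, D=%d features, %d classes\n",
              s$N, s$M, s$D, length(s$class_counts)))
  invisible(x)
}

n_instances <- function(tab) nrow(tab$features)
subject_of <- function(tab) tab$subject_id
group_key <- function(tab, level) {
  switch(level,
    subject = tab$subject_id,
    session = paste(tab$subject_id, tab$session_id, sep = "/"),
    trial   = {
      if (is.null(tab$trial_id))
        fail("trial level requested but the table has no trial_id column")
      paste(tab$subject_id, tab$session_id, tab$trial_id, sep = "/")
    },
    fail("unknown grouping level: ", level))
}

#' Summarize a sample table
#'
#' Exact counts at every level of the hierarchy: instances, subjects,
#' sessions per subject, instances per subject and per (subject, session),
#' and class counts (which always sum to N).
#'
#' @param object a [sample_table].
#' @param ... unused.
#' @return A list of class `sample_table_summary` with elements `N`, `M`,
#'   `D`, `n_groups_session`, `sessions_per_subject`,
#'   `instances_per_subject`, `instances_per_session`, `class_counts`.
#' @export
summary.sample_table <- function(object, ...) {
  subj <- object$subject_id
  sess <- group_key(object, "session")
  out <- list(
    N = n_instances(object),
    M = length(unique(subj)),
    D = ncol(object$features),
    n_groups_session = length(unique(sess)),
    sessions_per_subject =
      vapply(split(object$session_id, subj),
             function(s) length(unique(s)), integer(1)),
    instances_per_subject = table(subj),
    instances_per_session = table(sess),
    class_counts = table(object$labels))
  class(out) <- "sample_table_summary"
  out
}

#' @export
print.sample_table_summary <- function(x, ...) {
  cat(sprintf("N=%d  M=%d  D=%d  sessions=%d\n",
              x$N, x$M, x$D, x$n_groups_session))
  cat("class counts:\n"); print(x$class_counts)
  invisible(x)
}

#' Subset a sample table by row indices
#'
#' @param tab a [sample_table].
#' @param idx integer row indices to keep (order preserved).
#' @return A new [sample_table] with the selected rows; label levels are
#'   preserved.
#' @export
subset_table <- function(tab, idx) {
  structure(
    list(features   = tab$features[idx, , drop = FALSE],
         labels     = tab$labels[idx],
         subject_id = tab$subject_id[idx],
         session_id = tab$session_id[idx],
         trial_id   = if (is.null(tab$trial_id)) NULL else tab$trial_id[idx],
         time_index = tab$time_index[idx]),
    class = "sample_table")
}

#' Replace the labels of a sample table
#'
#' Used by the null controls: features and annotations are left untouched,
#' and the original labels are retained in attribute `original_labels` for
#' reporting.
#'
#' @param tab a [sample_table].
#' @param labels new length-`N` label vector.
#' @return The relabeled [sample_table].
#' @export
set_labels <- function(tab, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  assert_that(length(labels) == n_instances(tab),
              "labels must have one entry per row")
  out <- tab
  attr(out, "original_labels") <- tab$labels
  out$labels <- labels
  out
}

# ---- readers / writers ------------------------------------------------------

table_to_frame <- function(tab) {
  d <- ncol(tab$features)
  df <- data.frame(
    subject_id = tab$subject_id,
    session_id = tab$session_id,
    trial_id   = if (is.null(tab$trial_id)) "" else tab$trial_id,
    time_index = tab$time_index,
    label      = as.character(tab$labels),
    stringsAsFactors = FALSE)
  feat <- as.data.frame(tab$features)
  names(feat) <- paste0("feature_", seq_len(d) - 1L)
  cbind(df, feat)
}

frame_to_table <- function(df, path = "<data frame>") {
  required <- c("subject_id", "session_id", "time_index", "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    fail("schema error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  feat_cols <- grep("^feature_[0-9]+$", names(df), value = TRUE)
  if (!length(feat_cols))
    fail("schema error in ", path, ": no feature_* columns found")
  feat_cols <- feat_cols[order(as.integer(sub("feature_", "", feat_cols)))]
  trial <- NULL
  if ("trial_id" %in% names(df)) {
    tr <- as.character(df$trial_id)
    tr[is.na(tr)] <- ""
    if (any(tr != "")) trial <- tr
  }
  sample_table(as.matrix(df[feat_cols]),
               labels     = as.character(df$label),
               subject_id = df$subject_id,
               session_id = df$session_id,
               trial_id   = trial,
               time_index = df$time_index)
}

#' Read a sample table from CSV or HDF5
#'
#' CSV dialect: header row with columns `subject_id`, `session_id`,
#' `trial_id` (may be empty), `time_index`, `label`, then
#' `feature_0 ... feature_{D-1}`; UTF-8, `.` decimal separator. HDF5 layout:
#' a 2-D float dataset `features`, one 1-D dataset per annotation column,
#' and a string attribute `schema_version`. Row order is preserved from the
#' file. Missing columns raise a schema error naming the column; a
#' non-monotone time index raises a validation error citing the first
#' offending row.
#'
#' @param path file to read.
#' @param format `"csv"` or `"hdf5"`; defaults from the file extension.
#' @return A validated [sample_table].
#' @export
read_sample_table <- function(path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path)) "hdf5" else "csv"
  assert_that(file.exists(path), "file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    return(frame_to_table(df, path))
  }
  if (!requireNamespace("rhdf5", quietly = TRUE))
    fail("reading HDF5 requires the rhdf5 package")
  read1 <- function(name) as.vector(rhdf5::h5read(path, name))
  present <- rhdf5::h5ls(path)$name
  required <- c("features", "subject_id", "session_id", "time_index", "label")
  missing <- setdiff(required, present)
  if (length(missing))
    fail("schema error in ", path, ": missing required dataset(s) ",
         paste(missing, collapse = ", "))
  feats <- rhdf5::h5read(path, "features")
  trial <- if ("trial_id" %in% present) read1("trial_id") else NULL
  if (!is.null(trial) && all(trial == "")) trial <- NULL
  sample_table(feats,
               labels     = read1("label"),
               subject_id = read1("subject_id"),
               session_id = read1("session_id"),
               trial_id   = trial,
               time_index = read1("time_index"))
}

#' Write a sample table to CSV or HDF5
#'
#' Inverse of [read_sample_table]; `read_sample_table(write_sample_table(t))`
#' reproduces the table field-by-field for both formats (label levels are
#' stored by name and re-sorted on read).
#'
#' @param tab a [sample_table].
#' @param path output file.
#' @param format `"csv"` or `"hdf5"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tab, path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path)) "hdf5" else "csv"
  validate_sample_table(tab)
  if (format == "csv") {
    utils::write.csv(table_to_frame(tab), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(path))
  }
  if (!requireNamespace("rhdf5", quietly = TRUE))
    fail("writing HDF5 requires the rhdf5 package")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tab$features, path, "features")
  rhdf5::h5write(as.character(tab$labels), path, "label")
  rhdf5::h5write(tab$subject_id, path, "subject_id")
  rhdf5::h5write(tab$session_id, path, "session_id")
  rhdf5::h5write(tab$trial_id %||% rep("", n_instances(tab)), path, "trial_id")
  rhdf5::h5write(tab$time_index, path, "time_index")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("1.0", fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
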