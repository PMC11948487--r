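#' Null-control specification
#'
#' Describes one of the three label-randomization controls:
#'
#' * `"random_by_group"`: every instance in a group (subject or session)
#'   receives the same freshly drawn random label -- the group-constant
#'   random-label control. With `balanced = TRUE` (default) group counts
#'   per class differ by at most 1, so the optimal population-level
#'   accuracy is exactly the chance level.
#' * `"permute_sequences_across_subjects"`: whole label *sequences* are
#'   reassigned across subjects by a derangement, preserving each donor's
#'   temporal label structure while breaking the feature-label link.
#' * `"shuffle_instances"`: a uniform permutation of labels over all
#'   instances, the unstructured baseline.
#'
#' Every control conserves the feature matrix and time structure exactly;
#' only labels change.
#'
#' @param kind one of `"random_by_group"`,
#'   `"permute_sequences_across_subjects"`, `"shuffle_instances"`.
#' @param level `"subject"` or `"session"` (for `random_by_group`).
#' @param n_classes number of random classes (`>= 2`) for
#'   `random_by_group`.
#' @param balanced balance class counts across groups (default `TRUE`).
#' @param min_instances minimum instances a subject needs to enter the
#'   sequence permutation (default 1; 2000 is the conventional preset for
#'   whole-night sleep recordings).
#' @return A `null_spec` list.
#' @export
null_spec <- function(kind = c("random_by_group",
                               "permute_sequences_across_subjects",
                               "shuffle_instances"),
                      level = c("subject", "session"),
                      n_classes = 2L, balanced = TRUE,
                      min_instances = 1L) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  assert_that(min_instances >= 1, "min_instances must be >= 1")
  structure(list(kind = kind, level = level,
                 n_classes = as.integer(n_classes),
                 balanced = isTRUE(balanced),
                 min_instances = as.integer(min_instances)),
            class = "null_spec")
}

#' Assign group-constant random labels
#'
#' Every instance within a group at the chosen level carries the same
#' randomly drawn label; features and annotations are untouched, and the
#' true labels are retained in attribute `original_labels`. Balanced
#' assignment distributes classes over groups as evenly as possible (group
#' counts per class differ by at most 1); unbalanced assignment draws each
#' group's label iid uniform.
#'
#' @param tab a [sample_table].
#' @param level `"subject"` or `"session"`.
#' @param n_classes number of random classes (`>= 2`).
#' @param balanced balance classes over groups (default `TRUE`); requires
#'   at least `n_classes` groups.
#' @param seed integer seed.
#' @return The relabeled [sample_table] with classes `r1 ... rC`.
#' @export
assign_random_labels_by_group <- function(tab, level = c("subject", "session"),
                                          n_classes = 2L, balanced = TRUE,
                                          seed = 1L) {
  level <- match.arg(level)
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  g <- group_key(tab, level)
  groups <- unique(g)
  if (balanced && length(groups) < n_classes)
    fail("balanced assignment needs at least n_classes (", n_classes,
         ") groups at level '", level, "'; found ", length(groups))
  lab_of_group <- withr::with_seed(seed, {
    if (balanced) sample(rep(seq_len(n_classes), length.out = length(groups)))
    else sample.int(n_classes, length(groups), replace = TRUE)
  })
  names(lab_of_group) <- groups
  set_labels(tab, factor(paste0("r", lab_of_group[g]),
                         levels = paste0("r", seq_len(n_classes))))
}

# seeded derangement of 1..n (no fixed points)
derangement <- function(n, seed) {
  assert_that(n >= 2, "derangement needs n >= 2")
  withr::with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) return(p)
    }
  })
}

#' Permute label sequences across subjects
#'
#' Reassigns each eligible subject's complete label sequence (in time
#' order) to a different subject via a derangement, preserving the temporal
#' label structure -- run lengths, stage progressions -- while breaking the
#' link between a subject's features and its own labels. Subjects with
#' fewer than `min_instances` rows are dropped from the returned table.
#' When the donor sequence is longer than the recipient it is truncated;
#' when shorter it is recycled from its start, with a warning.
#'
#' @param tab a [sample_table].
#' @param min_instances eligibility threshold on per-subject instance
#'   count.
#' @param seed integer seed for the derangement.
#' @return The relabeled (and possibly row-subset) [sample_table]; true
#'   labels of the retained rows are in attribute `original_labels`.
#' @export
permute_label_sequences_across_subjects <- function(tab, min_instances = 1L,
                                                    seed = 1L) {
  counts <- table(tab$subject_id)
  eligible <- names(counts)[counts >= min_instances]
  if (length(eligible) < 2)
    fail("sequence permutation needs >= 2 subjects with at least ",
         min_instances, " instances; found ", length(eligible))
  keep <- which(tab$subject_id %in% eligible)
  tab2 <- subset_table(tab, keep)
  ord <- order(tab2$subject_id, tab2$session_id, tab2$time_index)
  seq_of <- lapply(split(ord, tab2$subject_id[ord]),
                   function(idx) as.character(tab2$labels[idx]))
  donors <- derangement(length(eligible), seed)
  new_labels <- character(n_instances(tab2))
  recycled <- FALSE
  for (i in seq_along(eligible)) {
    recip <- eligible[i]
    donor_seq <- seq_of[[eligible[donors[i]]]]
    rows <- ord[tab2$subject_id[ord] == recip]
    if (length(donor_seq) < length(rows)) recycled <- TRUE
    new_labels[rows] <- rep(donor_seq, length.out = length(rows))
  }
  if (recycled)
    warning("donor label sequence shorter than recipient; recycled from ",
            "its start", call. = FALSE)
  set_labels(tab2, factor(new_labels, levels = levels(tab2$labels)))
}

#' Uniformly shuffle labels over instances
#'
#' @param tab a [sample_table] with `N >= 2`.
#' @param seed integer seed.
#' @return The relabeled [sample_table]; class counts are conserved.
#' @export
shuffle_instances <- function(tab, seed = 1L) {
  n <- n_instances(tab)
  assert_that(n >= 2, "need at least 2 instances to shuffle")
  perm <- withr::with_seed(seed, sample.int(n))
  set_labels(tab, tab$labels[perm])
}

apply_null <- function(tab, null, seed) {
  switch(null$kind,
    random_by_group =
      assign_random_labels_by_group(tab, level = null$level,
                                    n_classes = null$n_classes,
                                    balanced = null$balanced, seed = seed),
    permute_sequences_across_subjects =
      permute_label_sequences_across_subjects(
        tab, min_instances = null$min_instances, seed = seed),
    shuffle_instances = shuffle_instances(tab, seed = seed),
    fail("unknown null kind: ", null$kind))
}

#' Permutation test of a cross-validated performance statistic
#'
#' Computes the observed statistic (mean fold metric of `model` under
#' `scheme`) on the true labels, then re-randomizes the labels `n_perm`
#' times under the chosen null control -- keeping the splitting scheme, the
#' features, and the time structure fixed -- and refits the full
#' cross-validation on each null label set. Which structure the null keeps
#' (instances, sessions, subjects, or whole temporal sequences) determines
#' which hypothesis is tested, so the null kind must be chosen to match the
#' claimed level of generalization.
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, which never returns 0.
#'
#' @param tab a [sample_table].
#' @param scheme a scheme specification (see [make_folds]); rebuilt once,
#'   after any eligibility filtering implied by the null, and then held
#'   fixed across permutations.
#' @param model a `classifier_spec`.
#' @param metric metric name as in [run_scheme].
#' @param null a [null_spec].
#' @param n_perm number of permutations (`>= 19`).
#' @param seed integer seed; all permutation seeds derive from it.
#' @return An object of class `null_result`: `observed`, `null_stats`,
#'   `p`, `n_perm`, `null`, `scheme`.
#' @export
permutation_test <- function(tab, scheme, model, metric = "accuracy",
                             null = null_spec("shuffle_instances"),
                             n_perm = 99L, seed = 1L) {
  assert_that(n_perm >= 19, "n_perm must be >= 19")
  if (null$kind == "permute_sequences_across_subjects") {
    counts <- table(tab$subject_id)
    keep <- names(counts)[counts >= null$min_instances]
    if (length(keep) < 2)
      fail("null incompatible with table: fewer than 2 subjects meet ",
           "min_instances = ", null$min_instances)
    tab <- subset_table(tab, which(tab$subject_id %in% keep))
  }
  fa <- make_folds(tab, scheme)
  observed <- run_scheme(tab, fa, model, metric)$mean
  null_stats <- vapply(seq_len(n_perm), function(b) {
    tb <- apply_null(tab, null, seed = derive_seed(seed, b))
    run_scheme(tb, fa, model, metric)$mean
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_stats = null_stats, p = p,
                 n_perm = as.integer(n_perm), null = null,
                 scheme = fa$scheme),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "<null_result> observed %.3f vs null %.3f (sd %.3f), p = %.4g (%d perms, %s)\n",
    x$observed, mean(x$null_stats), stats::sd(x$null_stats), x$p,
    x$n_perm, x$null$kind))
  invisible(x)
}

#' Serialize a null result to JSON
#' @param x a `null_result`.
#' @param path optional output file.
#' @return JSON text (observed, null array, p), or `path` invisibly.
#' @export
null_result_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(list(observed = x$observed,
                              null = x$null_stats, p = x$p,
                              n_perm = x$n_perm, kind = x$null$kind),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
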