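#' Fold assignments
#'
#' A `fold_assignment` realizes one data-splitting scheme as an ordered list
#' of (train, eval) index sets, plus the metadata needed to reproduce and
#' audit it. For every scheme except `no_validation` the eval sets are
#' pairwise disjoint and cover all eligible rows, each fold's train and eval
#' sets are disjoint, grouped schemes never split a group across train and
#' eval of the same fold, and time-blocked schemes keep each eval set
#' contiguous in time within every (subject, session). These contracts are
#' asserted by [check_fold_assignment], which every constructor runs.
#'
#' @name fold_assignment
#' @keywords internal
NULL

new_fold_assignment <- function(scheme, folds, k, tab, level = NULL,
                                seed = NULL, eligible = NULL, notes = NULL) {
  fa <- structure(
    list(scheme = scheme, level = level, k = k, seed = seed,
         folds = folds,
         n = n_instances(tab),
         eligible = eligible %||% seq_len(n_instances(tab)),
         notes = notes),
    class = "fold_assignment")
  check_fold_assignment(fa, tab)
  fa
}

#' Check the structural contracts of a fold assignment
#'
#' Universal checker run on every constructed assignment: disjointness of
#' train/eval within folds, pairwise-disjoint eval sets covering the
#' eligible rows (except `no_validation`), group integrity for grouped
#' schemes, and time contiguity for time-blocked schemes.
#'
#' @param fa a `fold_assignment`.
#' @param tab the [sample_table] it was built from.
#' @return `fa`, invisibly; errors on any violated contract.
#' @export
check_fold_assignment <- function(fa, tab) {
  idx_all <- unlist(lapply(fa$folds, function(f) c(f$train, f$eval)))
  assert_that(all(idx_all >= 1 & idx_all <= n_instances(tab)),
              "fold indices out of range for table")
  if (fa$scheme == "no_validation") return(invisible(fa))
  evals <- lapply(fa$folds, `[[`, "eval")
  for (f in fa$folds)
    assert_that(!length(intersect(f$train, f$eval)),
                "train and eval sets of a fold must be disjoint")
  ev <- unlist(evals)
  assert_that(!anyDuplicated(ev), "eval sets must be pairwise disjoint")
  assert_that(setequal(ev, fa$eligible),
              "eval sets must cover exactly the eligible rows")
  if (fa$scheme %in% c("group_kfold", "segment_3fold") && !is.null(fa$level)) {
    g <- group_key(tab, fa$level)
    for (f in fa$folds)
      assert_that(!length(intersect(unique(g[f$train]), unique(g[f$eval]))),
                  "group '", fa$level, "' split across train and eval")
  }
  if (fa$scheme == "time_kfold") {
    grp <- paste(tab$subject_id, tab$session_id, sep = "\r")
    for (f in fa$folds) {
      for (g in unique(grp[f$eval])) {
        rows <- intersect(f$eval, which(grp == g))
        ti <- sort(tab$time_index[rows])
        all_ti <- sort(tab$time_index[grp == g])
        pos <- match(ti, all_ti)
        assert_that(all(diff(pos) == 1),
                    "time_kfold eval block not contiguous within a session")
      }
    }
  }
  invisible(fa)
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> scheme=%s%s k=%d, %d eligible rows\n",
              x$scheme,
              if (!is.null(x$level)) paste0("(", x$level, ")") else "",
              x$k, length(x$eligible)))
  invisible(x)
}

# split n items into k near-equal blocks, remainder to the earliest blocks
block_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Diagnostic no-validation "split"
#'
#' One fold with train = eval = all rows, i.e. evaluating the classifier on
#' its own training data. Always flagged as inappropriate, diagnostic-only:
#' over-parameterized networks routinely drive the training metric to 1.0
#' regardless of generalization, so downstream reports annotate this row as
#' a bad-practice baseline rather than a performance estimate.
#'
#' @param tab a [sample_table].
#' @return A deterministic `fold_assignment` with `k = 1`.
#' @export
make_no_validation <- function(tab) {
  validate_sample_table(tab)
  idx <- seq_len(n_instances(tab))
  new_fold_assignment("no_validation",
                      list(list(train = idx, eval = idx)),
                      k = 1L, tab = tab,
                      notes = "no-validation: inappropriate, diagnostic only")
}

#' Instance-level K-fold cross-validation
#'
#' Each individual instance is assigned at random to one of `k` eval folds
#' (sizes differing by at most 1), ignoring all group structure -- the
#' scheme matched to "new instances from the same subject" questions, and
#' the one that leaks subject identity when targets are subject-constant.
#'
#' @param tab a [sample_table].
#' @param k number of folds (`2 <= k <= N`).
#' @param seed integer seed driving the permutation.
#' @param stratified if `TRUE`, per-class eval counts differ by at most 1
#'   across folds. Off by default.
#' @return A `fold_assignment`.
#' @export
make_instance_kfold <- function(tab, k, seed = 1L, stratified = FALSE) {
  validate_sample_table(tab)
  n <- n_instances(tab)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(k <= n, "k (", k, ") exceeds the number of instances (", n, ")")
  fold_of <- integer(n)
  if (stratified) {
    for (cl in levels(tab$labels)) {
      idx <- which(tab$labels == cl)
      perm <- withr::with_seed(derive_seed(seed, match(cl, levels(tab$labels))),
                               sample(idx))
      fold_of[perm] <- rep(seq_len(k), length.out = length(perm))
    }
  } else {
    perm <- withr::with_seed(seed, sample.int(n))
    fold_of[perm] <- rep(seq_len(k), length.out = n)
  }
  folds <- lapply(seq_len(k), function(j)
    list(train = which(fold_of != j), eval = which(fold_of == j)))
  new_fold_assignment("instance_kfold", folds, k = as.integer(k), tab = tab,
                      seed = as.integer(seed))
}

#' Group K-fold cross-validation
#'
#' Entire groups (subjects, sessions, or trials) are assigned to folds, so
#' no group ever contributes rows to both train and eval of the same fold.
#' Group-to-fold balancing is greedy: groups are taken largest first (ties
#' broken by a seeded shuffle) and each is placed in the fold currently
#' holding the fewest instances, which bounds fold-size disparity without
#' randomized search. For session- and trial-level splits the balancer
#' first spreads groups sharing a parent (a subject's sessions; a session's
#' trials) over distinct folds, because a session-level split is meant to
#' evaluate the same subject on a held-out session -- a subject whose
#' sessions all landed in one fold would be evaluated as an unseen subject
#' instead.
#'
#' @param tab a [sample_table].
#' @param level `"subject"`, `"session"`, or `"trial"`.
#' @param k number of folds; must not exceed the number of groups.
#' @param seed integer seed (tie-breaking among equal-sized groups).
#' @return A `fold_assignment`.
#' @export
make_group_kfold <- function(tab, level = c("subject", "session", "trial"),
                             k, seed = 1L) {
  level <- match.arg(level)
  validate_sample_table(tab)
  g <- group_key(tab, level)
  groups <- unique(g)
  assert_that(k >= 2, "k must be >= 2")
  if (length(groups) < k)
    fail("fewer ", level, " groups (", length(groups),
         ") than requested folds (", k, ")")
  sizes <- table(g)[groups]
  parent <- switch(level,
    subject = NULL,
    session = vapply(groups, function(gr)
      tab$subject_id[match(gr, g)], character(1)),
    trial   = vapply(groups, function(gr)
      paste(tab$subject_id, tab$session_id)[match(gr, g)], character(1)))
  ord <- withr::with_seed(seed, sample(seq_along(groups)))
  ord <- ord[order(-as.integer(sizes)[ord])]      # largest first, seeded ties
  fold_of_group <- integer(length(groups))
  totals <- numeric(k)
  parent_counts <- if (is.null(parent)) NULL else
    matrix(0L, k, length(unique(parent)),
           dimnames = list(NULL, unique(parent)))
  for (i in ord) {
    if (is.null(parent)) {
      j <- which.min(totals)
    } else {
      # spread a parent's groups over folds, then balance instance counts
      pc <- parent_counts[, parent[i]]
      cand <- which(pc == min(pc))
      j <- cand[which.min(totals[cand])]
      parent_counts[j, parent[i]] <- parent_counts[j, parent[i]] + 1L
    }
    fold_of_group[i] <- j
    totals[j] <- totals[j] + sizes[i]
  }
  names(fold_of_group) <- groups
  folds <- lapply(seq_len(k), function(j) {
    ev <- which(g %in% groups[fold_of_group == j])
    list(train = setdiff(seq_along(g), ev), eval = ev)
  })
  new_fold_assignment("group_kfold", folds, k = as.integer(k), tab = tab,
                      level = level, seed = as.integer(seed))
}

#' Time-blocked K-fold cross-validation
#'
#' Within each (subject, session), instances are cut in temporal order into
#' `k` contiguous near-equal blocks (remainder instances go to the earliest
#' blocks); fold `j` evaluates the union of block `j` over all sessions.
#' Deterministic -- there is no randomness to seed. This mimics deployment
#' on a chronological data stream and exposes temporal memorization.
#'
#' @param tab a [sample_table].
#' @param k number of blocks; every (subject, session) needs `>= k` rows.
#' @return A `fold_assignment`.
#' @export
make_time_kfold <- function(tab, k) {
  validate_sample_table(tab)
  assert_that(k >= 2, "k must be >= 2")
  grp <- paste(tab$subject_id, tab$session_id, sep = "\r")
  fold_of <- integer(n_instances(tab))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(tab$time_index[idx])]
    if (length(idx) < k)
      fail("subject/session (", sub("\r", ", ", g), ") has ", length(idx),
           " instances, fewer than k = ", k)
    fold_of[idx] <- rep(seq_len(k), times = block_sizes(length(idx), k))
  }
  folds <- lapply(seq_len(k), function(j)
    list(train = which(fold_of != j), eval = which(fold_of == j)))
  new_fold_assignment("time_kfold", folds, k = as.integer(k), tab = tab)
}

#' Segment 3-fold cross-validation over trials
#'
#' Within each (subject, session), trials are ordered by their first time
#' index and cut into three tertiles (first, middle, last; remainder trials
#' to the earliest tertiles). Fold `j` evaluates tertile `j` pooled across
#' all sessions and subjects, training on the other two -- the within-
#' subject segment scheme used for trial-structured recordings where each
#' session presents a fixed sequence of stimuli.
#'
#' @param tab a [sample_table] with `trial_id` present.
#' @return A deterministic `fold_assignment` with `k = 3`.
#' @export
make_segment_3fold <- function(tab) {
  validate_sample_table(tab)
  if (is.null(tab$trial_id))
    fail("segment 3-fold requires a trial_id column")
  grp <- paste(tab$subject_id, tab$session_id, sep = "\r")
  tertile <- integer(n_instances(tab))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    trials <- tab$trial_id[idx]
    first_t <- vapply(split(tab$time_index[idx], trials), min, numeric(1))
    ord_trials <- names(sort(first_t))
    tert_of_trial <- rep(1:3, times = block_sizes(length(ord_trials), 3L))
    names(tert_of_trial) <- ord_trials
    tertile[idx] <- tert_of_trial[trials]
  }
  folds <- lapply(1:3, function(j)
    list(train = which(tertile != j), eval = which(tertile == j)))
  new_fold_assignment("segment_3fold", folds, k = 3L, tab = tab,
                      level = "trial")
}

#' Build a fold assignment from a scheme specification
#'
#' Dispatcher used by nested cross-validation, the permutation-test runner
#' and the command-line interface. `spec` is a list with element `scheme`
#' (one of `"no_validation"`, `"instance_kfold"`, `"group_kfold"`,
#' `"time_kfold"`, `"segment_3fold"`) plus the scheme's own arguments
#' (`k`, `level`, `seed`, `stratified`).
#'
#' @param tab a [sample_table].
#' @param spec scheme specification list (an existing `fold_assignment` is
#'   returned unchanged).
#' @return A `fold_assignment`.
#' @export
make_folds <- function(tab, spec) {
  if (inherits(spec, "fold_assignment")) return(spec)
  assert_that(is.list(spec) && !is.null(spec$scheme),
              "spec must be a list with a 'scheme' element")
  switch(spec$scheme,
    no_validation  = make_no_validation(tab),
    instance_kfold = make_instance_kfold(tab, k = spec$k,
                                         seed = spec$seed %||% 1L,
                                         stratified = isTRUE(spec$stratified)),
    group_kfold    = make_group_kfold(tab, level = spec$level, k = spec$k,
                                      seed = spec$seed %||% 1L),
    time_kfold     = make_time_kfold(tab, k = spec$k),
    segment_3fold  = make_segment_3fold(tab),
    fail("unknown scheme: ", spec$scheme))
}

#' Nested cross-validation assignment
#'
#' For each outer fold, an inner fold assignment is built from that fold's
#' training rows only, so inner eval sets never intersect the outer eval
#' set. Model selection on the inner level keeps the outer estimate honest:
#' selecting a hyperparameter by inner score and reporting the outer-eval
#' score removes the winner's-curse optimism of selecting and reporting on
#' the same folds.
#'
#' @param tab a [sample_table].
#' @param outer scheme specification for the outer level (see [make_folds]).
#' @param inner scheme specification for the inner level, built within each
#'   outer training set.
#' @return An object of class `nested_assignment`: the outer
#'   `fold_assignment` plus one inner assignment per outer fold (with row
#'   indices mapped back to the full table).
#' @export
make_nested <- function(tab, outer, inner) {
  outer_fa <- make_folds(tab, outer)
  inners <- vector("list", outer_fa$k)
  for (j in seq_len(outer_fa$k)) {
    tr <- outer_fa$folds[[j]]$train
    sub <- subset_table(tab, tr)
    fa <- tryCatch(make_folds(sub, inner),
                   error = function(e)
                     fail("inner scheme infeasible on outer fold ", j, ": ",
                          conditionMessage(e)))
    fa$folds <- lapply(fa$folds, function(f)
      list(train = tr[f$train], eval = tr[f$eval]))
    fa$eligible <- tr[fa$eligible]
    inners[[j]] <- fa
  }
  structure(list(outer = outer_fa, inner = inners),
            class = "nested_assignment")
}

#' @export
print.nested_assignment <- function(x, ...) {
  cat(sprintf("<nested_assignment> outer %s k=%d, inner %s k=%d\n",
              x$outer$scheme, x$outer$k,
              x$inner[[1]]$scheme, x$inner[[1]]$k))
  invisible(x)
}

#' Serialize a fold assignment to a JSON fold map
#'
#' @param fa a `fold_assignment`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON text `{"fold_1": {"train": [...], "eval": [...]}, ...}`
#'   (1-based row indices).
#' @export
folds_to_json <- function(fa, path = NULL) {
  m <- stats::setNames(fa$folds, paste0("fold_", seq_along(fa$folds)))
  js <- jsonlite::toJSON(list(scheme = fa$scheme, level = fa$level,
                              k = fa$k, seed = fa$seed, folds = m),
                         auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
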