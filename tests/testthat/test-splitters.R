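test_that("no-validation is the flagged train-equals-eval diagnostic", {
  tab <- tiny_table(m = 1, n_per = 5, d = 1)
  fa <- make_no_validation(tab)
  expect_equal(fa$k, 1L)
  expect_equal(fa$folds[[1]]$train, 1:5)
  expect_equal(fa$folds[[1]]$eval, 1:5)
  expect_match(fa$notes, "diagnostic only")
  expect_identical(fa, make_no_validation(tab))   # no randomness
})

test_that("instance K-fold partitions evenly, deterministically, optionally stratified", {
  tab <- tiny_table(m = 2, n_per = 5, d = 1)    # N = 10
  fa <- make_instance_kfold(tab, k = 5, seed = 3)
  expect_equal(sort(lengths(lapply(fa$folds, `[[`, "eval"))), rep(2L, 5))
  expect_identical(fa, make_instance_kfold(tab, k = 5, seed = 3))
  expect_false(identical(fa$folds,
                         make_instance_kfold(tab, k = 5, seed = 4)$folds))
  expect_error(make_instance_kfold(tab, k = 11), "exceeds")

  # large-N arithmetic: 58135 instances, k = 5 -> five eval sets of 11627
  n <- 58135
  big <- sample_table(matrix(0, n, 1), labels = rep(c("a", "b"), length.out = n),
                      subject_id = rep("s1", n), session_id = rep("e1", n),
                      time_index = seq_len(n) - 1L)
  fb <- make_instance_kfold(big, k = 5, seed = 1)
  expect_equal(lengths(lapply(fb$folds, `[[`, "eval")), rep(11627L, 5))

  # stratified: per-class eval counts differ by at most 1 across folds
  lab <- rep(c("a", "a", "a", "b"), length.out = 40)
  tab2 <- tiny_table(m = 4, n_per = 10, d = 1, labels = lab)
  fs <- make_instance_kfold(tab2, k = 4, seed = 9, stratified = TRUE)
  for (cl in c("a", "b")) {
    per_fold <- vapply(fs$folds, function(f)
      sum(tab2$labels[f$eval] == cl), integer(1))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("group K-fold keeps groups whole and balances greedily", {
  tab <- tiny_table(m = 6, n_per = 4, d = 1)
  fa <- make_group_kfold(tab, "subject", k = 3, seed = 2)
  subj_of_fold <- lapply(fa$folds, function(f) unique(tab$subject_id[f$eval]))
  expect_equal(lengths(subj_of_fold), rep(2L, 3))
  expect_equal(anyDuplicated(unlist(subj_of_fold)), 0L)

  # session-level split with 3 sessions per subject: every subject
  # contributes distinct sessions to every fold's train and eval
  tab3 <- generate_samples(synth_config(M = 4, S = 3, n = 5, D = 2, seed = 5))
  f3 <- make_group_kfold(tab3, "session", k = 3, seed = 1)
  for (f in f3$folds) {
    expect_setequal(unique(tab3$subject_id[f$eval]), unique(tab3$subject_id))
    expect_setequal(unique(tab3$subject_id[f$train]), unique(tab3$subject_id))
    expect_length(intersect(unique(paste(tab3$subject_id, tab3$session_id)[f$eval]),
                            unique(paste(tab3$subject_id, tab3$session_id)[f$train])),
                  0)
  }

  # greedy largest-first balancing: sizes (100,60,40,40,30,30), k=3.
  # Hand-simulating largest-group-to-smallest-fold gives totals 100/90/110.
  sizes <- c(100, 60, 40, 40, 30, 30)
  subject <- rep(sprintf("g%d", seq_along(sizes)), times = sizes)
  n <- length(subject)
  tabg <- sample_table(matrix(0, n, 1), labels = rep(c("a", "b"), length.out = n),
                       subject_id = subject, session_id = rep("e1", n),
                       time_index = unlist(lapply(sizes, seq_len)) - 1L)
  fg <- make_group_kfold(tabg, "subject", k = 3, seed = 1)
  expect_equal(sort(lengths(lapply(fg$folds, `[[`, "eval"))), c(90, 100, 110))

  expect_error(make_group_kfold(tab, "subject", k = 7), "subject")
  expect_error(make_group_kfold(tab, "trial", k = 2), "trial_id")
})

test_that("time K-fold cuts contiguous ordered blocks with remainder to the earliest", {
  tab <- tiny_table(m = 1, n_per = 10, d = 1)
  fa <- make_time_kfold(tab, k = 5)
  expect_equal(lapply(fa$folds, `[[`, "eval"),
               list(1:2, 3:4, 5:6, 7:8, 9:10))

  tab11 <- tiny_table(m = 1, n_per = 11, d = 1,
                      labels = rep(c("a", "b"), length.out = 11))
  f11 <- make_time_kfold(tab11, k = 5)
  expect_equal(lengths(lapply(f11$folds, `[[`, "eval")), c(3L, 2L, 2L, 2L, 2L))

  # later folds never evaluate earlier instances of the same subject
  tab2 <- tiny_table(m = 3, n_per = 9, d = 1)
  f2 <- make_time_kfold(tab2, k = 3)
  for (subj in unique(tab2$subject_id)) {
    maxima <- vapply(f2$folds, function(f) {
      rows <- f$eval[tab2$subject_id[f$eval] == subj]
      max(tab2$time_index[rows])
    }, numeric(1))
    expect_true(all(diff(maxima) > 0))
  }

  expect_error(make_time_kfold(tiny_table(m = 1, n_per = 3), k = 5), "s01")
})

test_that("segment 3-fold cuts trial tertiles within each session", {
  tab <- trial_table(m = 2, s = 2, trials = 15, per_trial = 2)
  fa <- make_segment_3fold(tab)
  expect_equal(fa$k, 3L)
  for (f in fa$folds) {
    for (g in unique(paste(tab$subject_id, tab$session_id))) {
      rows <- f$eval[paste(tab$subject_id, tab$session_id)[f$eval] == g]
      expect_length(unique(tab$trial_id[rows]), 5)   # 15 trials -> 5 per tertile
    }
  }

  one <- trial_table(m = 1, s = 1, trials = 3, per_trial = 1)
  fo <- make_segment_3fold(one)
  expect_equal(lengths(lapply(fo$folds, `[[`, "eval")), rep(1L, 3))

  seven <- trial_table(m = 1, s = 1, trials = 7, per_trial = 1)
  f7 <- make_segment_3fold(seven)
  expect_equal(lengths(lapply(f7$folds, `[[`, "eval")), c(3L, 2L, 2L))

  expect_error(make_segment_3fold(tiny_table()), "trial_id")
})

test_that("nested assignments confine inner folds to the outer training set", {
  tab <- tiny_table(m = 10, n_per = 4, d = 2)
  na <- make_nested(tab,
                    outer = list(scheme = "group_kfold", level = "subject",
                                 k = 5, seed = 1),
                    inner = list(scheme = "group_kfold", level = "subject",
                                 k = 4, seed = 2))
  for (j in seq_len(na$outer$k)) {
    tr <- na$outer$folds[[j]]$train
    ev <- na$outer$folds[[j]]$eval
    inner <- na$inner[[j]]
    all_inner <- unlist(lapply(inner$folds, function(f) c(f$train, f$eval)))
    expect_length(intersect(all_inner, ev), 0)
    # union of inner eval sets is exactly the outer training set
    expect_setequal(unlist(lapply(inner$folds, `[[`, "eval")), tr)
    # inner folds only contain the 8 outer-training subjects
    expect_length(unique(tab$subject_id[all_inner]), 8)
  }
  expect_error(
    make_nested(tab,
                outer = list(scheme = "group_kfold", level = "subject",
                             k = 5, seed = 1),
                inner = list(scheme = "group_kfold", level = "subject",
                             k = 9, seed = 2)),
    "outer fold")
})

test_that("structural contracts hold on randomized tables", {
  for (seed in 1:40) {
    tab <- random_table(seed)
    n <- nrow(tab$features)
    m <- length(unique(tab$subject_id))
    fas <- list(make_instance_kfold(tab, k = 2, seed = seed),
                make_group_kfold(tab, "subject", k = 2, seed = seed))
    if (min(table(paste(tab$subject_id, tab$session_id))) >= 3)
      fas <- c(fas, list(make_time_kfold(tab, k = 3)))
    for (fa in fas) {
      # the universal checker enforces disjointness/coverage/grouping
      expect_silent(check_fold_assignment(fa, tab))
      expect_setequal(unlist(lapply(fa$folds, `[[`, "eval")), seq_len(n))
    }
    # group-to-fold map is a function: brute-force over rows
    fg <- fas[[2]]
    fold_of_row <- integer(n)
    for (j in seq_along(fg$folds)) fold_of_row[fg$folds[[j]]$eval] <- j
    expect_true(all(vapply(split(fold_of_row, tab$subject_id),
                           function(v) length(unique(v)) == 1, logical(1))))
  }
})
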