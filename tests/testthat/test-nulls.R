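test_that("group-constant random labels are constant within groups and balanced across them", {
  tab <- tiny_table(m = 4, n_per = 6, d = 2)
  rt <- assign_random_labels_by_group(tab, "subject", n_classes = 2,
                                      balanced = TRUE, seed = 5)
  per_subject <- vapply(split(as.character(rt$labels), rt$subject_id),
                        function(l) length(unique(l)), integer(1))
  expect_true(all(per_subject == 1))               # zero within-group variance
  subj_label <- vapply(split(as.character(rt$labels), rt$subject_id),
                       `[[`, character(1), 1)
  expect_equal(sort(unname(table(subj_label))), array(c(2L, 2L)))
  expect_identical(rt$features, tab$features)      # features untouched
  expect_identical(attr(rt, "original_labels"), tab$labels)

  # session-level: sessions constant, a subject's sessions may differ
  tab2 <- generate_samples(synth_config(M = 3, S = 2, n = 8, D = 2, seed = 2))
  rs <- assign_random_labels_by_group(tab2, "session", n_classes = 2,
                                      balanced = TRUE, seed = 4)
  per_session <- vapply(
    split(as.character(rs$labels), paste(rs$subject_id, rs$session_id)),
    function(l) length(unique(l)), integer(1))
  expect_true(all(per_session == 1))

  expect_error(assign_random_labels_by_group(tiny_table(m = 2), "subject",
                                             n_classes = 5, balanced = TRUE),
               "at least n_classes")
})

test_that("sequence permutation deranges subjects and preserves temporal label structure", {
  # two eligible subjects: labels are swapped (the only derangement)
  lab <- c("W", "W", "R", "R", "R", "N", "N", "N", "W", "W")
  tab <- tiny_table(m = 2, n_per = 5, d = 1, labels = lab)
  pt <- permute_label_sequences_across_subjects(tab, seed = 3)
  expect_equal(as.character(pt$labels), c(lab[6:10], lab[1:5]))
  expect_identical(pt$features, tab$features)
  expect_identical(pt$time_index, tab$time_index)

  # truncation: donor (W,W,R,R,R,W,W) feeding a 5-instance recipient
  feats <- matrix(0, 12, 1)
  tab2 <- sample_table(feats,
                       labels = c("N", "N", "N", "N", "N",
                                  "W", "W", "R", "R", "R", "W", "W"),
                       subject_id = rep(c("a", "b"), c(5, 7)),
                       session_id = rep("e1", 12),
                       time_index = c(0:4, 0:6))
  expect_warning(permute_label_sequences_across_subjects(tab2, seed = 1),
                 "recycled")
  p2 <- suppressWarnings(permute_label_sequences_across_subjects(tab2,
                                                                 seed = 1))
  expect_equal(as.character(p2$labels[p2$subject_id == "a"]),
               c("W", "W", "R", "R", "R"))
  # the shorter donor sequence is recycled for the longer recipient
  expect_equal(as.character(p2$labels[p2$subject_id == "b"]),
               c("N", "N", "N", "N", "N", "N", "N"))

  # run-length structure of each recipient equals its donor's (no recycling)
  tab3 <- generate_samples(synth_config(M = 4, S = 1, n = 30, D = 4, C = 3,
                                        label_scheme = "state", seed = 9))
  p3 <- permute_label_sequences_across_subjects(tab3, seed = 7)
  runs <- function(lbl) rle(as.character(lbl))$lengths
  donor_runs <- lapply(split(as.character(tab3$labels), tab3$subject_id), runs)
  for (subj in unique(p3$subject_id)) {
    got <- runs(p3$labels[p3$subject_id == subj])
    expect_true(any(vapply(donor_runs, identical, logical(1), got)))
  }

  # derangement property over seeds: no subject keeps its own sequence
  for (seed in 1:15) {
    p <- permute_label_sequences_across_subjects(tab3, seed = seed)
    for (subj in unique(p$subject_id)) {
      expect_false(identical(as.character(p$labels[p$subject_id == subj]),
                             as.character(tab3$labels[tab3$subject_id == subj])))
    }
  }

  # eligibility filter drops short subjects
  short <- tiny_table(m = 3, n_per = 4, d = 1)
  short$subject_id[1:4] <- "tiny"                  # still 4 instances
  expect_error(permute_label_sequences_across_subjects(short,
                                                       min_instances = 5),
               ">= 2 subjects")
})

test_that("instance shuffling conserves class counts and is seed-stable", {
  tab <- tiny_table(m = 2, n_per = 10, d = 1,
                    labels = rep(c("a", "a", "b", "c"), 5))
  sh <- shuffle_instances(tab, seed = 2)
  expect_equal(table(sh$labels), table(tab$labels))
  expect_identical(sh$features, tab$features)
  expect_identical(as.character(sh$labels),
                   as.character(shuffle_instances(tab, seed = 2)$labels))

  two <- tiny_table(m = 1, n_per = 2, d = 1, labels = c("a", "b"))
  s2 <- shuffle_instances(two, seed = 1)
  expect_true(identical(as.character(s2$labels), c("a", "b")) ||
                identical(as.character(s2$labels), c("b", "a")))
})

test_that("permutation test applies the add-one rule and is reproducible", {
  # strong real signal: observed beats all 99 nulls, p = 1/100
  tab <- generate_samples(synth_config(M = 4, S = 1, n = 25, D = 4, C = 2,
                                       label_scheme = "state", delta = 3,
                                       phi = 0, ar = 0, seed = 14))
  res <- permutation_test(tab,
                          scheme = list(scheme = "instance_kfold", k = 3,
                                        seed = 2),
                          model = centroid_classifier(),
                          metric = "accuracy",
                          null = null_spec("shuffle_instances"),
                          n_perm = 99, seed = 5)
  expect_equal(res$p, 0.01)
  expect_length(res$null_stats, 99)
  expect_gt(res$observed, max(res$null_stats))

  res2 <- permutation_test(tab,
                           scheme = list(scheme = "instance_kfold", k = 3,
                                         seed = 2),
                           model = centroid_classifier(),
                           metric = "accuracy",
                           null = null_spec("shuffle_instances"),
                           n_perm = 99, seed = 5)
  expect_identical(res$null_stats, res2$null_stats)

  expect_error(permutation_test(tab, list(scheme = "instance_kfold", k = 3),
                                centroid_classifier(),
                                null = null_spec("shuffle_instances"),
                                n_perm = 5), "n_perm")
  expect_error(
    permutation_test(tab, list(scheme = "instance_kfold", k = 3),
                     centroid_classifier(),
                     null = null_spec("permute_sequences_across_subjects",
                                      min_instances = 1000),
                     n_perm = 19),
    "min_instances")
})
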