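# A small but fingerprint-rich trait-labeled null table and a state-labeled
# table with real effect, shared across audit tests. The network is kept
# small; the phenomena it must show are qualitative.
audit_null_tab <- function(seed = 17)
  generate_samples(synth_config(M = 10, S = 1, n = 15, D = 8, C = 2,
                                label_scheme = "trait", delta = 0, phi = 5,
                                ar = 0, seed = seed))
audit_spec <- function() mlp_classifier(hidden_units = 16, epochs = 120,
                                        seed = 2)

test_that("identity probes decode identity under instance splits and are refused under group splits", {
  tab <- audit_null_tab()
  pr <- identity_probe(tab, "subject",
                       list(scheme = "instance_kfold", k = 5, seed = 1),
                       audit_spec())
  expect_gt(pr$mean, 3 * attr(pr, "chance")$theoretical)   # >> 1/M
  expect_equal(attr(pr, "n_identities"), 10)

  expect_error(
    identity_probe(tab, "subject",
                   list(scheme = "group_kfold", level = "subject", k = 5,
                        seed = 1), audit_spec()),
    "impossible")

  # no fingerprints: probe cannot beat chance by much
  flat <- generate_samples(synth_config(M = 10, S = 1, n = 15, D = 8, C = 2,
                                        label_scheme = "trait", delta = 0,
                                        phi = 0, ar = 0, seed = 18))
  pf <- identity_probe(flat, "subject",
                       list(scheme = "instance_kfold", k = 5, seed = 1),
                       audit_spec())
  expect_lt(pf$mean, 0.3)
})

test_that("the audit flags memorization without generalization on null trait data", {
  rep1 <- run_audit(audit_null_tab(), question = "c", spec = audit_spec(),
                    k = 5, seed = 3)
  expect_true(rep1$flags$identity_memorization)
  expect_true(rep1$flags$no_signal)
  # instance split inflated far above the subject-level scheme
  expect_gt(rep1$schemes$instance_kfold$mean, rep1$schemes$matched$mean)

  # deterministic re-run: identical serialized report
  rep2 <- run_audit(audit_null_tab(), question = "c", spec = audit_spec(),
                    k = 5, seed = 3)
  expect_identical(render_report(rep1, "json"), render_report(rep2, "json"))
})

test_that("a real state effect under question (a) raises no flags", {
  tab <- generate_samples(synth_config(M = 8, S = 1, n = 20, D = 8, C = 2,
                                       label_scheme = "state", delta = 2,
                                       phi = 1, ar = 0.3, seed = 19))
  rep <- run_audit(tab, question = "a", spec = audit_spec(), k = 5, seed = 4)
  expect_false(rep$flags$leakage_suspicion)
  expect_false(rep$flags$identity_memorization)
  expect_false(rep$flags$no_signal)
})

test_that("infeasible questions fail with an explanation", {
  single_session <- audit_null_tab()
  expect_error(run_audit(single_session, question = "b"),
               "multiple sessions")
  few <- generate_samples(synth_config(M = 3, S = 1, n = 10, D = 4, seed = 1))
  expect_error(run_audit(few, question = "c", k = 5), "at least k")
})

test_that("reports render as a results table in markdown and round-trip through JSON", {
  rep <- run_audit(audit_null_tab(), question = "c", spec = audit_spec(),
                   k = 5, seed = 3)
  md <- render_report(rep, "markdown")
  expect_match(md, "No validation \\*\\(diagnostic only\\)\\*")
  expect_match(md, "\\d\\.\\d{3} \\(\\d\\.\\d{3}\\)")      # mean (sd) cells
  expect_match(md, "not assessable from single-source data")
  expect_match(md, "corrected resampled t-test")

  js <- render_report(rep, "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$schemes$instance_kfold$mean,
               rep$schemes$instance_kfold$mean)
  expect_equal(parsed$flags$no_signal, rep$flags$no_signal)
  # serialization is stable: parse -> re-serialize -> parse is a fixed point
  expect_equal(jsonlite::fromJSON(js), parsed)
})

test_that("flag false positives stay controlled when fingerprints are absent", {
  fired <- vapply(1:5, function(seed) {
    tab <- generate_samples(synth_config(M = 10, S = 1, n = 12, D = 6, C = 2,
                                         label_scheme = "trait", delta = 0,
                                         phi = 0, ar = 0, seed = 100 + seed))
    run_audit(tab, question = "c",
              spec = centroid_classifier(),
              k = 5, seed = seed)$flags$identity_memorization
  }, logical(1))
  expect_lte(sum(fired), 1)
})

test_that("nested selection removes the optimism of naive single-level selection", {
  # hyperparameter: which single feature the centroid model may use.
  # On null data the naive best-of-D cross-validated score is optimistic;
  # nested selection scores the chosen feature on untouched outer folds.
  naive_vs_nested <- function(seed) {
    tab <- generate_samples(synth_config(M = 6, S = 1, n = 10, D = 6, C = 2,
                                         label_scheme = "trait", delta = 0,
                                         phi = 0, ar = 0, seed = seed))
    cv_acc <- function(t, fa) run_scheme(t, fa, centroid_classifier())$mean
    feat_tab <- function(t, j) {
      t$features <- t$features[, j, drop = FALSE]
      t
    }
    fa <- make_instance_kfold(tab, k = 3, seed = seed)
    naive <- max(vapply(1:6, function(j) cv_acc(feat_tab(tab, j), fa),
                        numeric(1)))
    outer <- make_instance_kfold(tab, k = 3, seed = seed + 1)
    nested <- mean(vapply(seq_len(outer$k), function(o) {
      tr <- outer$folds[[o]]$train
      sub <- subset_table(tab, tr)
      inner <- make_instance_kfold(sub, k = 3, seed = seed + 2)
      best <- which.max(vapply(1:6, function(j)
        cv_acc(feat_tab(sub, j), inner), numeric(1)))
      ft <- feat_tab(tab, best)
      m <- fit_classifier(centroid_classifier(), ft$features[tr, , drop = FALSE],
                          ft$labels[tr])
      ev <- outer$folds[[o]]$eval
      accuracy(predicted_classes(predict_scores(m, ft$features[ev, , drop = FALSE])),
               ft$labels[ev])
    }, numeric(1)))
    c(naive = naive, nested = nested)
  }
  res <- vapply(1:40, naive_vs_nested, numeric(2))
  expect_gt(mean(res["naive", ]), 0.5 + 0.03)   # selection optimism
  expect_lt(abs(mean(res["nested", ]) - 0.5),
            abs(mean(res["naive", ]) - 0.5))    # nested closer to truth
})
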