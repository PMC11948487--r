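#' Identity probe: predict subject or session identity from features
#'
#' Trains the classifier to predict the subject (or session) identity of
#' each instance, quantifying how strongly identity is encoded in the
#' features -- the mechanism behind leakage when targets are constant
#' within a subject. Probing an identity under a scheme that holds that
#' same identity out (e.g. subject identity under subject group K-fold) is
#' rejected as impossible: a model cannot predict classes it never saw.
#'
#' @param tab a [sample_table].
#' @param target `"subject"` or `"session"`.
#' @param scheme scheme specification or `fold_assignment`.
#' @param spec a `classifier_spec`.
#' @return A `fold_scores` object for multiclass accuracy, with the chance
#'   level for the number of identities attached as attribute `chance`.
#' @export
identity_probe <- function(tab, target = c("subject", "session"),
                           scheme, spec) {
  target <- match.arg(target)
  fa <- make_folds(tab, scheme)
  if (fa$scheme == "group_kfold" && !is.null(fa$level)) {
    blocked <- (target == "subject" && fa$level %in% c("subject")) ||
      (target == "session" && fa$level %in% c("subject", "session"))
    if (blocked)
      fail(target, "-identity probe under ", fa$level, " group K-fold is ",
           "impossible: held-out ", fa$level, "s contain identities absent ",
           "from training")
  }
  ids <- group_key(tab, target)
  probe_tab <- set_labels(tab, factor(ids))
  res <- run_scheme(probe_tab, fa, spec, metric = "accuracy")
  attr(res, "chance") <- chance_level(
    n = max(1L, floor(n_instances(tab) / max(fa$k, 1L))),
    class_priors = as.vector(table(ids) / length(ids)))
  attr(res, "n_identities") <- length(unique(ids))
  res
}

question_scheme <- function(question, k, seed) {
  switch(question,
    a = list(scheme = "instance_kfold", k = k, seed = seed),
    b = list(scheme = "group_kfold", level = "session", k = k, seed = seed),
    c = list(scheme = "group_kfold", level = "subject", k = k, seed = seed),
    fail("unknown question: ", question))
}

question_text <- c(
  a = "generalization to new instances from the same subjects",
  b = "generalization to a new session from the same subjects",
  c = "generalization to new subjects from the same source")

#' Run the full validation audit battery
#'
#' Orchestrates the diagnostics for one scientific question:
#'
#' * `question = "a"`: new instances from seen subjects (instance K-fold is
#'   the matched scheme);
#' * `"b"`: a new session from seen subjects (session group K-fold);
#' * `"c"`: new subjects (subject group K-fold).
#'
#' The battery runs the no-validation diagnostic, instance K-fold, the
#' question-matched scheme, and time K-fold; identity probes (subject
#' always, session when the table has several sessions per subject); and
#' the random-label control at the question's grouping level evaluated
#' under the instance split (group-constant random labels for questions
#' (b) and (c); an instance-level label shuffle for question (a), which has
#' no group to hold constant). Three flags are raised from recorded
#' numeric comparisons:
#'
#' * `leakage_suspicion`: instance-split performance exceeds the matched
#'   scheme's, with non-overlapping mean +/- sd intervals and corrected
#'   resampled t-test p < 0.05;
#' * `identity_memorization`: instance-split performance on group-constant
#'   random labels exceeds the analytic chance bound;
#' * `no_signal`: the question-matched scheme does not beat the analytic
#'   chance bound.
#'
#' A fourth question -- new subjects at a new center -- is reported as not
#' assessable from single-source data rather than omitted.
#'
#' @param tab a [sample_table].
#' @param question `"a"`, `"b"`, or `"c"`.
#' @param spec a `classifier_spec` (default: the reference network).
#' @param metric metric name as in [run_scheme].
#' @param k fold count for the K-fold schemes.
#' @param seed integer seed; every stochastic component's seed derives
#'   from it and is echoed in the report.
#' @param alpha significance level for chance bounds and the corrected
#'   t-test.
#' @return An object of class `audit_report`.
#' @export
run_audit <- function(tab, question = c("a", "b", "c"),
                      spec = mlp_classifier(), metric = "accuracy",
                      k = 5L, seed = 1L, alpha = 0.05) {
  question <- match.arg(question)
  validate_sample_table(tab)
  s <- summary(tab)
  if (question == "b" && all(s$sessions_per_subject < 2))
    fail("question (b) requires multiple sessions per subject; ",
         "every subject has a single session")
  if (question == "c" && s$M < k)
    fail("question (c) requires at least k = ", k, " subjects; found ", s$M)

  matched_spec <- question_scheme(question, k, derive_seed(seed, 1))
  schemes <- list(
    no_validation = make_no_validation(tab),
    instance_kfold = make_instance_kfold(tab, k, derive_seed(seed, 2)))
  if (question != "a")
    schemes$matched <- make_folds(tab, matched_spec)
  min_per_session <- min(table(paste(tab$subject_id, tab$session_id)))
  if (min_per_session >= k)
    schemes$time_kfold <- make_time_kfold(tab, k)

  scores <- lapply(schemes, function(fa) run_scheme(tab, fa, spec, metric))
  matched_name <- if (question == "a") "instance_kfold" else "matched"

  # identity probes under the instance split (the regime where identity
  # leaks); subject probes under subject-grouped schemes are impossible.
  probes <- list(
    subject = identity_probe(tab, "subject", schemes$instance_kfold, spec))
  if (any(s$sessions_per_subject > 1))
    probes$session <- identity_probe(tab, "session",
                                     schemes$instance_kfold, spec)

  # random-label control at the question's grouping level, evaluated under
  # the instance split. Questions (b)/(c): group-constant random labels at
  # session/subject level. Question (a) has no group to hold constant, so
  # the control is an instance-level label shuffle.
  if (question == "a") {
    null_level <- "instance"
    n_rand_classes <- nlevels(droplevels(tab$labels))
    rand_tab <- shuffle_instances(tab, seed = derive_seed(seed, 3))
  } else {
    null_level <- if (question == "b") "session" else "subject"
    n_groups <- if (null_level == "subject") s$M else s$n_groups_session
    n_rand_classes <- min(nlevels(tab$labels), n_groups)
    rand_tab <- assign_random_labels_by_group(
      tab, level = null_level, n_classes = n_rand_classes,
      balanced = TRUE, seed = derive_seed(seed, 3))
  }
  rand_scores <- run_scheme(rand_tab, schemes$instance_kfold, spec, metric)

  chance <- chance_level(n = max(1L, floor(s$N / k)),
                         class_priors = as.vector(s$class_counts / s$N),
                         alpha = alpha)
  rand_chance <- chance_level(
    n = max(1L, floor(s$N / k)),
    class_priors = if (question == "a")
      as.vector(s$class_counts / s$N) else rep(1 / n_rand_classes,
                                               n_rand_classes),
    alpha = alpha)

  # corrected t-test on the instance-vs-matched fold contrast
  ttest <- NULL
  if (question != "a") {
    diffs <- scores$instance_kfold$fold_values - scores$matched$fold_values
    ttest <- tryCatch(corrected_ttest(diffs),
                      error = function(e) conditionMessage(e))
  }

  int_lo <- function(fs) fs$mean - (if (is.na(fs$sd)) 0 else fs$sd)
  int_hi <- function(fs) fs$mean + (if (is.na(fs$sd)) 0 else fs$sd)
  flags <- list(
    leakage_suspicion = question != "a" &&
      inherits(ttest, "corrected_ttest") &&
      int_lo(scores$instance_kfold) > int_hi(scores$matched) &&
      ttest$p < alpha,
    identity_memorization =
      rand_scores$mean > rand_chance$analytic_bound,
    no_signal = scores[[matched_name]]$mean <= chance$analytic_bound)

  structure(list(
    question = question,
    question_map = c(question_text,
                     d = paste("generalization to a new center:",
                               "not assessable from single-source data")),
    metric = metric,
    summary = s,
    schemes = scores,
    matched_scheme = matched_name,
    probes = probes,
    null_control = list(level = null_level, n_classes = n_rand_classes,
                        instance_split = rand_scores,
                        chance = rand_chance),
    chance = chance,
    ttest = ttest,
    flags = flags,
    provenance = list(seed = seed, k = k, alpha = alpha,
                      classifier = unclass(spec),
                      classifier_class = class(spec)[1],
                      package_version =
                        as.character(utils::packageVersion("nerveaudit")))),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(render_report(x, "markdown"))
  invisible(x)
}

fmt_cell <- function(fs) {
  if (is.null(fs)) return("N/A")
  sprintf("%.3f (%s)", fs$mean,
          if (is.na(fs$sd)) "N/A" else sprintf("%.3f", fs$sd))
}

#' Render an audit report
#'
#' Markdown output mirrors the familiar results-table layout: one row per
#' validation procedure, one column per target/metric, fold standard
#' deviations in parentheses, with the no-validation row annotated as
#' diagnostic-only. JSON output is loss-free and reload-stable.
#'
#' @param report an `audit_report`.
#' @param format `"markdown"` or `"json"`.
#' @return A character scalar (markdown) or JSON string.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                            digits = NA, null = "null", pretty = TRUE))
  }
  r <- report
  scheme_label <- c(no_validation = "No validation *(diagnostic only)*",
                    instance_kfold = "Instance K-fold",
                    matched = "Question-matched group K-fold",
                    time_kfold = "Time K-fold")
  probe_cell <- function(nm, scheme)
    if (!is.null(r$probes[[nm]]) && scheme == "instance_kfold")
      fmt_cell(r$probes[[nm]]) else "N/A"
  lines <- c(
    sprintf("# Validation audit (question %s)", r$question),
    "",
    sprintf("Question: %s.", r$question_map[[r$question]]),
    sprintf("Classifier: %s; metric: %s; k = %d; seed = %d.",
            r$provenance$classifier_class, r$metric, r$provenance$k,
            r$provenance$seed),
    "",
    sprintf("| Validation procedure | Target/%s | Subject ID/Acc. | Random by %s/Acc. |",
            r$metric, r$null_control$level),
    "|---|---|---|---|")
  for (nm in names(r$schemes)) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |",
      scheme_label[[nm]] %||% nm,
      fmt_cell(r$schemes[[nm]]),
      probe_cell("subject", nm),
      if (nm == "instance_kfold") fmt_cell(r$null_control$instance_split)
      else "N/A"))
  }
  lines <- c(lines, "",
    sprintf("Chance: theoretical %.3f; significant above %.3f (alpha = %.3g, n = %d).",
            r$chance$theoretical, r$chance$analytic_bound, r$chance$alpha,
            r$chance$n))
  if (inherits(r$ttest, "corrected_ttest")) {
    tt <- r$ttest
    lines <- c(lines, sprintf(
      "Instance vs matched scheme (corrected resampled t-test): d = %.3f [95%% CI %.3f, %.3f], t(%d) = %.2f, p = %.4g.",
      tt$mean_diff, tt$conf_int[1], tt$conf_int[2], tt$df, tt$t, tt$p))
  }
  lines <- c(lines, "", "## Flags", "")
  for (nm in names(r$flags))
    lines <- c(lines, sprintf("- %s: **%s**", nm,
                              if (isTRUE(r$flags[[nm]])) "raised" else "clear"))
  lines <- c(lines, "",
             paste0("Question (d): ", r$question_map[["d"]], "."), "")
  paste(lines, collapse = "\n")
}

# strip environments/functions so the report serializes losslessly
report_to_list <- function(r) {
  strip_fs <- function(fs) {
    if (is.null(fs)) return(NULL)
    list(metric = fs$metric, fold_values = fs$fold_values, mean = fs$mean,
         sd = fs$sd, scheme = fs$scheme, level = fs$level, k = fs$k,
         notes = fs$notes, chance = attr(fs, "chance")[c("theoretical",
                                                         "analytic_bound")])
  }
  list(question = r$question,
       question_map = as.list(r$question_map),
       metric = r$metric,
       summary = list(N = r$summary$N, M = r$summary$M, D = r$summary$D,
                      class_counts = as.list(unclass(r$summary$class_counts))),
       schemes = lapply(r$schemes, strip_fs),
       matched_scheme = r$matched_scheme,
       probes = lapply(r$probes, strip_fs),
       null_control = list(level = r$null_control$level,
                           n_classes = r$null_control$n_classes,
                           instance_split =
                             strip_fs(r$null_control$instance_split),
                           chance = unclass(r$null_control$chance)),
       chance = unclass(r$chance),
       ttest = if (inherits(r$ttest, "corrected_ttest"))
         unclass(r$ttest) else r$ttest,
       flags = r$flags,
       provenance = r$provenance)
}
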