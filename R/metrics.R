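#' Classification accuracy
#'
#' Fraction of exact matches between predictions and truth.
#'
#' @param predicted,truth equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  assert_that(length(truth) >= 1, "need at least one instance")
  mean(as.character(predicted) == as.character(truth))
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls; coincides with [accuracy] on
#' class-balanced truth and resists class imbalance (a majority-class
#' always-prediction on 90/10 data scores 0.5, not 0.9). Classes absent
#' from `truth` are dropped with a warning.
#'
#' @inheritParams accuracy
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, truth) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  truth <- as.factor(truth)
  present <- levels(truth)[tabulate(truth, nlevels(truth)) > 0]
  if (length(present) < nlevels(truth))
    warning("class(es) absent from truth dropped from balanced accuracy",
            call. = FALSE)
  assert_that(length(present) >= 1, "no class present in truth")
  recalls <- vapply(present, function(cl) {
    idx <- truth == cl
    mean(as.character(predicted)[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Rank-based binary AUC
#'
#' Area under the receiver operating characteristic curve via the
#' rank-sum (Mann-Whitney) estimator with midrank tie handling: the
#' probability that a random positive outscores a random negative, counting
#' ties as 1/2. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric score vector (larger = more positive).
#' @param truth binary truth: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return AUC in `[0, 1]`; 1 is a perfect classifier, 0.5 is chance.
#' @export
auc_binary <- function(scores, truth) {
  assert_that(length(scores) == length(truth),
              "scores and truth must have equal length")
  if (is.factor(truth)) truth <- truth == levels(truth)[2]
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    fail("AUC undefined: truth contains a single class")
  r <- rank(scores)           # midranks
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Chance-level estimate for classification accuracy
#'
#' Theoretical chance level under best-naive guessing is the largest class
#' prior (1/C under uniform priors). For a finite eval set of size `n` the
#' analytic significance bound is the smallest accuracy `a/n` whose
#' binomial upper-tail probability at success rate equal to the theoretical
#' level is at most `alpha` -- the accuracy a no-information classifier
#' exceeds with probability at most `alpha`. The bound is at least the
#' theoretical level and converges to it as `n` grows.
#'
#' @param n eval-set size (`>= 1`).
#' @param class_priors class prior probabilities, summing to 1; a single
#'   integer `C` is shorthand for uniform priors over `C` classes.
#' @param alpha significance level in `(0, 1)`.
#' @return A list of class `chance_estimate`: `theoretical`,
#'   `analytic_bound`, `n`, `alpha`.
#' @export
chance_level <- function(n, class_priors, alpha = 0.05) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  if (length(class_priors) == 1 && class_priors >= 2 &&
      class_priors == round(class_priors))
    class_priors <- rep(1 / class_priors, class_priors)
  assert_that(all(class_priors >= 0) &&
                abs(sum(class_priors) - 1) < 1e-8,
              "class priors must be non-negative and sum to 1")
  p0 <- max(class_priors)
  # smallest a with P(X >= a) <= alpha, X ~ Binomial(n, p0)
  upper_tail <- stats::pbinom(0:n - 1, n, p0, lower.tail = FALSE)
  a <- which(upper_tail <= alpha)[1] - 1L
  if (is.na(a)) a <- n + 1L   # alpha so small no count suffices; bound > 1
  structure(list(theoretical = p0, analytic_bound = a / n,
                 n = as.integer(n), alpha = alpha),
            class = "chance_estimate")
}

#' @export
print.chance_estimate <- function(x, ...) {
  cat(sprintf(
    "<chance_estimate> theoretical %.3f; accuracy > %.3f significant at alpha=%.3g (n=%d)\n",
    x$theoretical, x$analytic_bound, x$alpha, x$n))
  invisible(x)
}

corrected_se <- function(sd_d, k, c) sqrt(sd_d^2 * (1 / k + c))

#' Corrected resampled t-test on fold-wise metric differences
#'
#' Paired comparison of two evaluation procedures from their k fold-wise
#' metric differences. Because cross-validation folds share training data,
#' the fold differences are positively correlated and the naive paired
#' t-test is anticonservative. The correction inflates the variance of the
#' mean difference to `sigma_d^2 * (1/k + c)`. With
#' `rho_mode = "one_over_k"` the fold correlation is approximated as
#' `rho = 1/k`, giving `c = rho * (k-1)/k`; with
#' `rho_mode = "test_train_ratio"` the classical `c = n2/n1`
#' (eval-to-train size ratio) is used. Degrees of freedom are `k - 1`.
#'
#' @param fold_diffs length-`k` numeric vector of per-fold differences
#'   (procedure A minus procedure B, same folds).
#' @param rho_mode `"one_over_k"` (default) or `"test_train_ratio"`.
#' @param test_train_ratio eval/train size ratio `n2/n1`, required for
#'   `rho_mode = "test_train_ratio"`.
#' @return A list of class `corrected_ttest`: `mean_diff`, `sd_diff`,
#'   `k`, `c`, `se`, `t`, `df`, `p` (two-sided), `conf_int` (95%).
#' @export
corrected_ttest <- function(fold_diffs,
                            rho_mode = c("one_over_k", "test_train_ratio"),
                            test_train_ratio = NULL) {
  rho_mode <- match.arg(rho_mode)
  k <- length(fold_diffs)
  assert_that(k >= 2, "need at least 2 fold differences")
  dbar <- mean(fold_diffs)
  sd_d <- stats::sd(fold_diffs)
  if (sd_d == 0) fail("degenerate variance: all fold differences identical")
  c_term <- switch(rho_mode,
    one_over_k = (1 / k) * (k - 1) / k,
    test_train_ratio = {
      assert_that(!is.null(test_train_ratio) && test_train_ratio >= 0,
                  "test_train_ratio required and must be >= 0")
      test_train_ratio
    })
  se <- corrected_se(sd_d, k, c_term)
  tval <- dbar / se
  df <- k - 1
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- dbar + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(mean_diff = dbar, sd_diff = sd_d, k = k, c = c_term,
                 rho_mode = rho_mode, se = se, t = tval, df = df, p = p,
                 conf_int = ci),
            class = "corrected_ttest")
}

#' @export
print.corrected_ttest <- function(x, ...) {
  cat(sprintf(
    "<corrected_ttest> d=%.4f [95%% CI %.4f, %.4f], t(%d)=%.3f, p=%.4g (%s)\n",
    x$mean_diff, x$conf_int[1], x$conf_int[2], x$df, x$t, x$p, x$rho_mode))
  invisible(x)
}

#' Recover test statistics from a reported mean difference and CI
#'
#' Given a published mean fold-wise difference with its 95% confidence
#' interval and degrees of freedom, recovers the standard error
#' `(ci_high - ci_low) / (2 t_{0.975, df})`, the t statistic, and the
#' two-sided p-value. An asymmetric interval (beyond a small tolerance)
#' triggers a warning and the half-width mean is used.
#'
#' @param mean_diff reported mean difference.
#' @param ci_low,ci_high reported 95% CI endpoints
#'   (`ci_low < mean_diff < ci_high`).
#' @param df degrees of freedom (`>= 1`).
#' @return A list with `se`, `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean_diff, ci_low, ci_high, df) {
  assert_that(df >= 1, "df must be >= 1")
  assert_that(ci_low < mean_diff && mean_diff < ci_high,
              "CI must bracket the mean difference")
  width <- ci_high - ci_low
  center <- (ci_high + ci_low) / 2
  if (abs(center - mean_diff) > 1e-3 * width) {
    warning("confidence interval not symmetric about the mean; ",
            "using its half-width", call. = FALSE)
  }
  se <- width / (2 * stats::qt(0.975, df))
  tval <- mean_diff / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(se = se, t = tval, df = as.integer(df), p = p)
}
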