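---
title: "Auditing cross-validation on hierarchical neural data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cross-validation on hierarchical neural data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerveaudit)
```

## The problem

Electrophysiology and other biomedical studies rarely produce independent
samples. A typical dataset has `M` subjects (often 16--26), each recorded
over one or a few sessions, with each session epoched into hundreds or
thousands of feature vectors ("instances"). Instances from one subject
share a subject-specific component of the feature distribution -- a
*fingerprint* strong enough that brains are discussed as biometrics -- plus
session offsets and temporal autocorrelation. When the prediction target is
constant within a subject (a trait, a diagnosis, a genotype), a classifier
evaluated with instance-level cross-validation can score near-perfectly by
memorizing *which subject* an instance came from, while telling us nothing
about whether the target is decodable in a new subject. This package
implements the audit battery that exposes that failure mode and the
statistics needed to report honest performance.

## Splitting schemes and the questions they answer

Each splitting scheme estimates generalization at a different level, and
each level corresponds to a different scientific question:

| Question | Scheme | Constructor |
|---|---|---|
| (a) new instances, same subject | instance K-fold | `make_instance_kfold()` |
| (b) new session, same subject | session group K-fold | `make_group_kfold(level = "session")` |
| (c) new subject, same source | subject group K-fold | `make_group_kfold(level = "subject")` |
| temporal robustness | time K-fold | `make_time_kfold()` |
| trial-sequence designs | segment 3-fold | `make_segment_3fold()` |
| (d) new center | --- | not assessable from single-source data |

Every constructed assignment passes a universal structural checker: eval
sets are pairwise disjoint and cover the eligible rows, train and eval are
disjoint within folds, grouped schemes never split a group, and
time-blocked eval sets are contiguous in time within each
(subject, session). `make_no_validation()` -- train equals eval -- is
provided purely as a diagnostic of overfitting capacity and is annotated as
such wherever it appears.

Design choices that the problem left open:

* **Group balancing.** Groups are assigned to folds greedily, largest
  group first into the currently least-loaded fold, which bounds fold-size
  disparity deterministically. For session- and trial-level splits the
  balancer first spreads groups sharing a parent (a subject's sessions, a
  session's trials) over distinct folds: a session-level split is supposed
  to evaluate a *seen* subject on a held-out session, and a subject whose
  sessions all landed in one fold would silently be evaluated as an unseen
  subject instead. Subject-level splits use the pure greedy rule.
* **Stratification.** Instance K-fold shuffles without stratification by
  default; class-stratified assignment is an opt-in flag, since the
  classical procedure being audited is the unstratified one.
* **Remainders.** When instances or trials do not divide evenly, remainder
  elements go to the *earliest* blocks -- deterministic and
  order-preserving.
* **Nested cross-validation** (`make_nested()`) builds an inner assignment
  from each outer training set only. The test suite verifies, on null
  data, that selecting a hyperparameter on inner folds and scoring on the
  outer fold removes the winner's-curse optimism of selecting and
  reporting on the same cross-validation scores.

## Null controls

Three label randomizations, all of which leave the feature matrix and time
structure untouched:

* `assign_random_labels_by_group()` gives every instance of a subject (or
  session) the same freshly drawn label. Balanced assignment (classes
  spread over groups as evenly as possible) is the default. Note a
  subtlety we document because the audit itself would flag it: with
  *balanced* assignment and a small number of groups, group-level
  cross-validation of a memorizing classifier is pessimistically biased by
  roughly O(1/M) -- each training fold under-represents exactly the classes
  in its eval fold. Drawing each group's label independently (the
  `balanced = FALSE` variant) makes eval labels independent of everything
  the model sees, so its expected group-CV accuracy is exactly the chance
  level; the chance-recovery checks in the test suite therefore use the
  independent variant.
* `permute_label_sequences_across_subjects()` reassigns whole label
  sequences across subjects by a derangement (no subject keeps its own
  sequence), preserving temporal label structure -- run lengths, stage
  progressions -- while severing the feature-label link. Donor sequences
  longer than the recipient are truncated; shorter ones are recycled from
  the start with a warning. An instance-count eligibility threshold
  (`min_instances`) handles designs with very unequal recording lengths;
  2000 is the conventional preset for whole-night sleep recordings.
* `shuffle_instances()` is the unstructured uniform shuffle.

`permutation_test()` wraps any of these in an add-one permutation test,
`p = (1 + #{null >= observed}) / (n_perm + 1)`, holding the splitting
scheme fixed across permutations. Which structure the null *keeps* decides
which hypothesis is tested; permuting instances answers a different
question than permuting subjects.

## The reference classifier

The reference model is a single-hidden-layer perceptron with rectified
linear units and a softmax cross-entropy objective, trained by full-batch
Adam (`mlp_classifier()`; width presets of 10 for low-dimensional feature
sets and 256 for rich ones). There is deliberately **no early stopping**:
early stopping would itself consume a validation split, and the
over-parameterized zero-training-error regime is exactly what the
no-validation diagnostic needs to exhibit. Training is deterministic given
(spec, data, seed) and order-invariant under full-batch updates.
Per-fold feature standardization is estimated on the training rows only
and applied unchanged to eval rows -- the test suite includes a poisoning
test proving that corrupting eval rows cannot change a fold's fitted
model. The classifier contract (`fit_classifier()` / `predict_scores()`)
is pluggable; `centroid_classifier()` is a fast deterministic baseline
used where thousands of refits are needed.

## Metrics, chance levels, and the corrected t-test

`accuracy()`, `balanced_accuracy()` (unweighted mean of per-class recalls,
for imbalanced eval sets) and `auc_binary()` (rank-based, midrank ties)
are provided. Multiclass AUC is deliberately not a default; accuracy is
the conventional multiclass report.

`chance_level()` returns both the theoretical level (the largest class
prior; 1/C under uniform priors) and the analytic finite-sample bound: the
smallest accuracy whose binomial upper-tail probability at the theoretical
level is at most `alpha`. For example, with 100 eval instances and two
balanced classes, accuracies up to 0.58 are compatible with guessing at
the 5% level. The bound is non-increasing in `n` and converges to the
theoretical level.

`corrected_ttest()` compares two procedures from their k fold-wise metric
differences. Folds share training data, so the differences are positively
correlated and the classical paired t-test is anticonservative. The
corrected variance of the mean difference is `sigma_d^2 * (1/k + c)`; with
the fold correlation approximated as `rho = 1/k` (the default),
`c = rho (k-1)/k`, and the classical eval/train size ratio `c = n2/n1` is
available as an alternative. Degrees of freedom are `k - 1`, consistent
with df = 4 at k = 5; with `c = 0` the procedure reduces exactly to the
classical one-sample t-test, which the test suite checks to 1e-10.
`ttest_from_summary()` recovers `se`, `t` and `p` from a published mean
difference and confidence interval -- the worked example
`ttest_from_summary(0.064, 0.013, 0.115, df = 4)` returns p close to
0.025.

## The synthetic-data generator

`generate_samples()` produces the hierarchical structure the audits need,
with fully separable mechanisms:

```
x = delta * mu(y) + phi * u_subject + psi * v_session + eps
```

* `mu(y)`: orthonormal class templates (the label signal, scaled by the
  effect size `delta`; `delta = 0` is an exact null by construction);
* `u_subject`, `v_session`: unit-norm random directions drawn orthogonal
  to the template span, scaled by the fingerprint strength `phi` and the
  session offset `psi`. Orthogonalization is a deliberate idealization:
  real datasets entangle identity and label signal, but controlled tests
  need `delta` and `phi` to be independently tunable dials.
* `eps`: stationary AR(1) Gaussian noise within each session (coefficient
  `ar`, marginal scale `noise_scale`) -- the simplest model that reproduces
  temporal memorization under time-blocked splits.

Labels are instance-varying (`"state"`: a sticky Markov chain with stay
probability `p_stay`, emulating sleep-stage-like runs), subject-constant
(`"trait"`), or session-constant (`"session_trait"`).

**What counts as a "strong" fingerprint.** `phi` is meaningful only
relative to the noise radius `noise_scale * sqrt(D)`. We calibrated the
fingerprint-rich regime once, by the phenomenon it must emulate: an
instance-level subject-identity probe should identify the source subject
roughly 95% of the time, as reported for real electrophysiology features.
With `D = 16`, unit noise and `M = 20`, that is `phi = 5`
(between-subject separation `phi * sqrt(2) ≈ 7` against a noise radius of
4); `phi = 3` gives a probe accuracy near 0.6 and is *not*
fingerprint-rich. `verify_structure()` reports the empirical lag-1
autocorrelation, state stickiness and between-subject separation of any
generated table.

What the generator does **not** emulate: raw waveforms, spectral feature
realism (band powers, coherence), electrode montages, artifacts, class
imbalance drift, or entanglement between identity and label signal.
Passing audits on this generator therefore demonstrates the *mechanics* of
leakage and its detection, not performance on any real recording.

## The audit and its flags

`run_audit()` runs the battery for one question: the diagnostic
no-validation row, instance K-fold, the question-matched scheme, time
K-fold when the table has enough temporal depth, identity probes under the
instance split, and the random-label control at the question's grouping
level (for question (a), which has no group to hold constant, an
instance-level shuffle). Three flags are raised, each traceable to a
recorded numeric comparison:

1. **leakage_suspicion** -- instance-split performance exceeds the
   question-matched scheme's with non-overlapping mean ± sd intervals *and*
   corrected-t p < 0.05. Two criteria are required because no single
   threshold is canonical; both numbers are always reported.
2. **identity_memorization** -- instance-split performance on
   group-constant random labels exceeds the analytic chance bound: the
   pipeline can reproduce labels that carry no information.
3. **no_signal** -- the question-matched scheme does not beat the analytic
   chance bound: no evidence of signal at the claimed generalization
   level.

Reports render as markdown (the familiar rows-by-procedure,
parenthesized-fold-sd table) or loss-free JSON; provenance (seeds, config,
package version) is embedded so a report can be regenerated
bit-identically. The machine-readable NERVE-ML reporting checklist ships
as a versioned JSON schema (five categories, 38 items);
`checklist_validate()` checks responses for completeness and renders them.

## Numerical choices and problem sizes

* Seeds: every stochastic component takes an explicit integer seed; child
  seeds are derived arithmetically (kept below 2^31) and echoed in
  reports. All randomness is scoped -- no function disturbs the caller's
  RNG state.
* Ties: argmax class prediction breaks ties toward the first class; AUC
  uses midranks; zero-variance features standardize to scale 1.
* Degenerate inputs fail fast with named errors: single-class training
  labels, all-identical fold differences (the t-test is undefined),
  too-few groups for a requested k, probing an identity a group scheme
  holds out.
* The test suite and the reproduction script run the chance-recovery
  studies at M = 20 subjects, 25 instances per subject, D = 16 features,
  a 32-unit network and 20--30 seeds, and the Monte-Carlo calibration
  checks (permutation type-I error, nested-selection optimism) with the
  centroid baseline at a few hundred replicates. These sizes were chosen
  as the smallest at which the phenomena are stable across seeds; the
  mechanisms themselves are size-free.

## Limitations

The corrected t-test's `rho = 1/k` is an approximation with no exact
finite-sample guarantee; confidence intervals for cross-validated AUC are
not provided (interval construction under fold dependence is an open
problem); leave-one-group-out is expressed as group K-fold with k equal
to the number of groups rather than as a separate scheme; and multi-center
(question (d)) designs are out of scope -- the audit reports them as not
assessable from single-source data.
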