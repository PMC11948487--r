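#' Configuration for the hierarchical synthetic-data generator
#'
#' Describes a population of `M` subjects with `S` sessions each and `n`
#' instances per session, producing `N = M * S * n` rows of `D` features.
#' The feature model is
#'
#'   x = delta * mu(y) + phi * u_subject + psi * v_session + eps
#'
#' where `mu(y)` are orthonormal class templates, `u_subject` and
#' `v_session` are unit-norm random direction vectors per subject and per
#' session drawn orthogonal to the template span (so label signal and
#' fingerprints are separable mechanisms), and `eps` is Gaussian noise with
#' an order-1 autoregressive structure (coefficient `ar`) within each
#' session, stationary with marginal scale `noise_scale`.
#'
#' Labels per scheme: `"state"` is a sticky C-state Markov chain over time
#' within each session (stay probability `p_stay`, otherwise uniform over
#' the remaining states), emulating slowly switching behavioral or sleep
#' states; `"trait"` assigns one label per subject, balanced across
#' subjects; `"session_trait"` assigns one label per session, balanced
#' across sessions.
#'
#' @param M subjects.
#' @param S sessions per subject.
#' @param n instances per session.
#' @param D feature dimension.
#' @param C number of classes (`>= 2`).
#' @param label_scheme `"state"`, `"trait"`, or `"session_trait"`.
#' @param delta label-to-feature effect size (`>= 0`; 0 = exact null).
#' @param phi subject fingerprint strength (`>= 0`).
#' @param psi session offset strength (`>= 0`).
#' @param ar temporal noise autocorrelation, in `[0, 1)`.
#' @param p_stay state-label stay probability, in `[0, 1)`.
#' @param noise_scale marginal noise standard deviation.
#' @param seed integer seed; generation is fully seed-deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(M = 20L, S = 1L, n = 50L, D = 16L, C = 2L,
                         label_scheme = c("state", "trait", "session_trait"),
                         delta = 1, phi = 2, psi = 0.5, ar = 0.5,
                         p_stay = 0.9, noise_scale = 1, seed = 1L) {
  label_scheme <- match.arg(label_scheme)
  cfg <- list(M = as.integer(M), S = as.integer(S), n = as.integer(n),
              D = as.integer(D), C = as.integer(C),
              label_scheme = label_scheme,
              delta = delta, phi = phi, psi = psi, ar = ar,
              p_stay = p_stay, noise_scale = noise_scale,
              seed = as.integer(seed))
  assert_that(cfg$M >= 1 && cfg$S >= 1 && cfg$n >= 1, "M, S, n must be >= 1")
  assert_that(cfg$C >= 2, "C must be >= 2")
  assert_that(cfg$D >= cfg$C, "D must be >= C to fit orthonormal templates")
  assert_that(delta >= 0 && phi >= 0 && psi >= 0 && noise_scale > 0,
              "scales must be non-negative and noise_scale positive")
  assert_that(ar >= 0 && ar < 1, "ar must lie in [0, 1)")
  assert_that(p_stay >= 0 && p_stay < 1, "p_stay must lie in [0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

# random unit vector orthogonal to the columns of basis (NULL = none)
rand_unit <- function(d, basis = NULL) {
  v <- stats::rnorm(d)
  if (!is.null(basis)) v <- v - basis %*% crossprod(basis, v)
  v <- as.vector(v)
  v / sqrt(sum(v^2))
}

# stationary AR(1) series with marginal sd `sigma`
ar1_noise <- function(n, d, a, sigma) {
  z <- matrix(stats::rnorm(n * d), n, d)
  if (a == 0) return(sigma * z)
  out <- matrix(0, n, d)
  out[1, ] <- z[1, ]
  innov <- sqrt(1 - a^2)
  for (t in seq_len(n)[-1]) out[t, ] <- a * out[t - 1, ] + innov * z[t, ]
  sigma * out
}

# balanced assignment of C classes to n_units units, seeded shuffle
balanced_classes <- function(n_units, C) {
  sample(rep(seq_len(C), length.out = n_units))
}

#' Generate a hierarchical synthetic sample table
#'
#' Realizes the configuration described in [synth_config]: subject
#' fingerprints, session offsets, AR(1) feature noise, and state-, trait-,
#' or session-linked labels. With `delta = 0` the labels carry no feature
#' information by construction, giving an exact null in which any
#' above-chance group-level performance is a defect of the evaluation, not
#' of the data.
#'
#' @param config a [synth_config].
#' @return A [sample_table] with subjects `s01, s02, ...`, sessions
#'   `e1, ...`, class labels `c1 ... cC`, and `time_index` `0 ... n-1`
#'   within each session.
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    templates <- qr.Q(qr(matrix(stats::rnorm(cf$D * cf$C), cf$D, cf$C)))
    u_subj <- vapply(seq_len(cf$M), function(i) rand_unit(cf$D, templates),
                     numeric(cf$D))
    v_sess <- array(vapply(seq_len(cf$M * cf$S),
                           function(i) rand_unit(cf$D, templates),
                           numeric(cf$D)),
                    dim = c(cf$D, cf$S, cf$M))
    subj_trait <- balanced_classes(cf$M, cf$C)
    sess_trait <- matrix(balanced_classes(cf$M * cf$S, cf$C), cf$S, cf$M)

    rows <- vector("list", cf$M * cf$S)
    r <- 0L
    for (m in seq_len(cf$M)) {
      for (s in seq_len(cf$S)) {
        y <- switch(cf$label_scheme,
          trait = rep(subj_trait[m], cf$n),
          session_trait = rep(sess_trait[s, m], cf$n),
          state = {
            lab <- integer(cf$n)
            lab[1] <- sample.int(cf$C, 1)
            for (t in seq_len(cf$n)[-1]) {
              lab[t] <- if (stats::runif(1) < cf$p_stay) lab[t - 1] else
                sample(setdiff(seq_len(cf$C), lab[t - 1]), 1)
            }
            lab
          })
        eps <- ar1_noise(cf$n, cf$D, cf$ar, cf$noise_scale)
        x <- cf$delta * t(templates[, y, drop = FALSE]) +
          matrix(cf$phi * u_subj[, m], cf$n, cf$D, byrow = TRUE) +
          matrix(cf$psi * v_sess[, s, m], cf$n, cf$D, byrow = TRUE) +
          eps
        r <- r + 1L
        rows[[r]] <- list(x = x, y = y, m = m, s = s)
      }
    }
    feats <- do.call(rbind, lapply(rows, `[[`, "x"))
    sample_table(
      feats,
      labels     = factor(paste0("c", unlist(lapply(rows, `[[`, "y"))),
                          levels = paste0("c", seq_len(cf$C))),
      subject_id = sprintf("s%02d", unlist(lapply(rows, function(r)
        rep(r$m, cf$n)))),
      session_id = paste0("e", unlist(lapply(rows, function(r)
        rep(r$s, cf$n)))),
      time_index = unlist(lapply(rows, function(r) seq_len(cf$n) - 1L)))
  })
}

#' Empirical diagnostics of a generated table
#'
#' Reports how faithfully a generated table realizes its configuration:
#' mean within-session lag-1 feature autocorrelation, the empirical
#' stay frequency of state labels (NA for trait schemes), and the mean
#' between-subject centroid distance as a fingerprint separation measure.
#'
#' @param tab a [sample_table] produced by [generate_samples].
#' @param config the [synth_config] used.
#' @return A list with `lag1_autocorrelation`, `stay_fraction`,
#'   `between_subject_distance`, and the noise-only expectation
#'   `null_between_subject_distance` (distance expected when `phi = 0`,
#'   from the noise scale and per-subject sample size).
#' @export
verify_structure <- function(tab, config) {
  grp <- paste(tab$subject_id, tab$session_id, sep = "\r")
  acs <- unlist(lapply(split(seq_along(grp), grp), function(idx) {
    idx <- idx[order(tab$time_index[idx])]
    x <- tab$features[idx, , drop = FALSE]
    if (nrow(x) < 3) return(NULL)
    apply(x, 2, function(col) {
      if (stats::sd(col) == 0) return(NA_real_)
      stats::cor(col[-1], col[-length(col)])
    })
  }))
  stay <- NA_real_
  if (config$label_scheme == "state") {
    trans <- unlist(lapply(split(seq_along(grp), grp), function(idx) {
      idx <- idx[order(tab$time_index[idx])]
      y <- tab$labels[idx]
      y[-1] == y[-length(y)]
    }))
    stay <- mean(trans)
  }
  cent <- do.call(rbind,
                  lapply(split(seq_along(tab$subject_id), tab$subject_id),
                         function(idx)
                           colMeans(tab$features[idx, , drop = FALSE])))
  dmat <- as.matrix(stats::dist(cent))
  n_per <- mean(table(tab$subject_id))
  list(lag1_autocorrelation = mean(acs, na.rm = TRUE),
       stay_fraction = stay,
       between_subject_distance = mean(dmat[upper.tri(dmat)]),
       null_between_subject_distance =
         config$noise_scale * sqrt(2 * config$D / n_per))
}
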