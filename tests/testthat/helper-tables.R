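# Small deterministic tables built in code for unit tests.

# n_per instances for each of m subjects, one session each, d features
tiny_table <- function(m = 2, n_per = 5, d = 3, labels = NULL, seed = 42) {
  n <- m * n_per
  feats <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  if (is.null(labels))
    labels <- rep(c("a", "b"), length.out = n)
  sample_table(feats,
               labels = labels,
               subject_id = rep(sprintf("s%02d", seq_len(m)), each = n_per),
               session_id = rep("e1", n),
               time_index = rep(seq_len(n_per) - 1L, m))
}

# subjects x sessions x trials table with trial time structure
trial_table <- function(m = 2, s = 2, trials = 6, per_trial = 2, d = 2,
                        seed = 7) {
  n <- m * s * trials * per_trial
  feats <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  subject <- rep(sprintf("s%02d", seq_len(m)), each = s * trials * per_trial)
  session <- rep(rep(paste0("e", seq_len(s)), each = trials * per_trial), m)
  trial <- rep(rep(sprintf("t%02d", seq_len(trials)), each = per_trial), m * s)
  time <- rep(seq_len(trials * per_trial) - 1L, m * s)
  sample_table(feats, labels = rep(c("x", "y"), length.out = n),
               subject_id = subject, session_id = session,
               trial_id = trial, time_index = time)
}

# a random small table for property-style loops: random numbers of
# subjects/sessions/instances, valid by construction
random_table <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(2:6, 1)
    d <- sample(1:4, 1)
    rows <- list()
    subject <- session <- character(0)
    time <- integer(0)
    for (i in seq_len(m)) {
      for (s in seq_len(sample(1:3, 1))) {
        n_i <- sample(3:9, 1)
        subject <- c(subject, rep(sprintf("s%02d", i), n_i))
        session <- c(session, rep(paste0("e", s), n_i))
        time <- c(time, sort(sample(0:40, n_i)))
      }
    }
    n <- length(subject)
    sample_table(matrix(rnorm(n * d), n, d),
                 labels = sample(c("a", "b", "c"), n, replace = TRUE),
                 subject_id = subject, session_id = session,
                 time_index = time)
  })
}

expect_same_table <- function(a, b) {
  expect_equal(a$features, b$features, ignore_attr = TRUE)
  expect_equal(as.character(a$labels), as.character(b$labels))
  expect_equal(levels(a$labels), levels(b$labels))
  expect_equal(a$subject_id, b$subject_id)
  expect_equal(a$session_id, b$session_id)
  expect_equal(a$trial_id, b$trial_id)
  expect_equal(a$time_index, b$time_index)
}
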