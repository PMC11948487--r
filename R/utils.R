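# Internal helpers shared across modules.

# Deterministically derive a child seed from a base seed and an offset.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + 104729 * (offset %% m)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a message assembled from parts (keeps call sites compact).
fail <- function(...) stop(paste0(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) fail(...)
  invisible(TRUE)
}
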