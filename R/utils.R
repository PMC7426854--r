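# Internal helpers: seeding, argument checks.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# Draw `n` child seeds from a parent seed, all < 2^31.
child_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  if (!is.numeric(x) || anyNA(x))
    stop_bad_arg(name, "must be numeric and non-missing")
  lo <- if (open_left) x <= 0 else x < 0
  hi <- if (open_right) x >= 1 else x > 1
  if (any(lo | hi)) {
    b <- sprintf("must lie in %s0, 1%s",
                 if (open_left) "(" else "[", if (open_right) ")" else "]")
    stop_bad_arg(name, b)
  }
  invisible(x)
}
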