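# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream label, so
# every stochastic operation inside a run draws from its own named stream.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, label) {
  chars <- utf8ToInt(label)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 * 48271 + h) %% 2147483562 + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}
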