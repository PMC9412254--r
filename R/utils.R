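# Internal helpers: argument checking and seeded evaluation.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single non-missing number", name)
  if (finite && !is.finite(x)) stopf("`%s` must be finite", name)
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (x <= 0) stopf("`%s` must be strictly positive (got %g)", name, x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}
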