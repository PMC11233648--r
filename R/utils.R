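# Internal helpers shared across the package.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream label; keeps values well
# inside 32-bit integer range so they are valid set.seed() inputs.
child_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483562) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ccgnet <- function(...) stop(..., call. = FALSE)
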