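# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed; keeps values well inside 32-bit range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483587
}

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
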