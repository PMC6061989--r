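# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package calls never disturb user-level
# random streams. `seed = NULL` means "use the ambient RNG as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Locale-independent lexicographic order (C collation) so feature tables are
# identical across platforms.
c_order <- function(x) order(x, method = "radix")

# Derive independent sub-seeds from a master seed, each below 2^31.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
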