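# internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic derived seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 999983 * as.double(offset)) %% 2147483647)
}
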