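## Internal helpers.

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so seeded generators have no side effects.
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a child seed from a base seed and a stream index, kept inside the
## 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 104729 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
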