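# Seed handling: every stochastic operation takes an explicit integer seed and
# runs in a local RNG scope, so calling it never disturbs the caller's RNG
# stream and identical seeds give identical results.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed below 2^31 from a parent seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}
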