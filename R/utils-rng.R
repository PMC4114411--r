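# Seed handling: every source of randomness flows through explicit seeds so
# identical invocations give byte-identical output. with_seed_() evaluates an
# expression under a seed and restores the caller's RNG state; rng_stream()
# is a tiny Lehmer generator used to derive independent sub-seeds (one per
# perturbation draw, fold shuffle, ...) from a single run seed, keeping all
# derived seeds below 2^31.

with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  expr
}

rng_stream <- function(seed) {
  m <- 2147483647
  state <- as.double(seed) %% m
  if (state <= 0) state <- state + (m - 1)
  nxt <- function() {
    state <<- (state * 48271) %% m
    as.integer(state)
  }
  list(
    next_seed = nxt,
    sample_int = function(n, k) with_seed_(nxt(), sample.int(n, k))
  )
}
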