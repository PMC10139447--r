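# Self-contained RNG streams: every stochastic operation takes an explicit
# seed and never disturbs the caller's .Random.seed.

local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  g <- globalenv()
  old <- get0(".Random.seed", envir = g, inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = g)
  if (is.null(old)) rm(".Random.seed", envir = g)
  else assign(".Random.seed", old, envir = g)

  with_state <- function(expr) {
    old <- get0(".Random.seed", envir = g, inherits = FALSE)
    assign(".Random.seed", env$state, envir = g)
    on.exit({
      env$state <- get(".Random.seed", envir = g)
      if (is.null(old)) rm(".Random.seed", envir = g)
      else assign(".Random.seed", old, envir = g)
    })
    expr
  }
  list(
    unif = function(min = 0, max = 1, n = 1L) with_state(runif(n, min, max)),
    norm = function(n = 1L, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    int  = function(n) with_state(sample.int(n, 1L)),
    runif_n = function(n) with_state(runif(n))
  )
}
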