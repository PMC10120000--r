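# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs the user's stream.
# seed = NULL means "use the current stream as-is".
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Uniform sample of n points in the unit ball (radius 1, origin-centred):
# isotropic direction times radius ~ U^(1/3).
runif_ball <- function(n) {
  z <- matrix(stats::rnorm(3L * n), ncol = 3L)
  z <- z / sqrt(rowSums(z^2))
  z * stats::runif(n)^(1 / 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
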