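# Internal helpers.

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package route through this so
# that a scene/acquisition seed fully determines the output.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Relative L2 distance between two arrays of equal shape.
rel_l2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)
}
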