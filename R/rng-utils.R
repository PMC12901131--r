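# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
# All stochastic operators in the package route through this so that equal
# seeds give bit-identical output without disturbing the global RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a child seed from a parent seed and a stream index, keeping the
# result a valid positive 32-bit integer
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}
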