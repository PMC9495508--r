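# Small internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
.with_seed <- function(seed, expr) {
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

# Derive a per-stream 32-bit seed from a base seed and a stream index.
.derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629 + 1
}
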