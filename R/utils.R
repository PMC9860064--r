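# Small internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; with seed = NULL the code just runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a base seed and a stage/item index,
# kept inside the 32-bit integer range set.seed accepts.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 10007) %% 2147483647)
}
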