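# Internal numeric helpers shared across modules.

# Round half away from zero (R's round() is round-half-even, which would
# map 45.5 to 46 only by accident of representation).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

clip255 <- function(x) pmin(255, pmax(0, x))

# Deterministic substream derivation: mixes a study seed with arbitrary
# tokens (indices, id strings) into an integer seed < 2^31. Linear
# congruential mixing keeps every intermediate below 2^53 so the double
# arithmetic is exact. Adding tokens for one physician never perturbs the
# stream derived for another.
mixSeed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), function(t) {
    if (is.character(t)) utf8ToInt(paste(t, collapse = "\x1f")) else as.numeric(t)
  }), use.names = FALSE)
  h <- as.numeric(seed) %% 2147483629
  for (t in tokens) h <- (h * 69069 + (abs(t) %% 2147483629) + 1) %% 2147483629
  as.integer(h %% 2147483562) + 1L
}

# Evaluate expr under a given seed without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}
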