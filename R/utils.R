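# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v^2))
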