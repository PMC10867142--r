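# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(expr)
}

db_floor <- -120

# Amplitude (linear, re full scale) to dB, floored so silence never yields -Inf.
amp_to_db <- function(a) {
  pmax(20 * log10(pmax(a, 0)), db_floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
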