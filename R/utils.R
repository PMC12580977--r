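# Internal helpers shared across modules.

# Typed conditions: every user-facing error carries a specific class under
# the "laurdanGP_error" umbrella so callers (and the CLI) can dispatch on it.
stop_typed <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "laurdanGP_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
run_with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream seed derivation: mixes a base seed with integer
# indices (replicate, temperature index, scan index, ...) so that any subset
# of a simulated series is reproducible in isolation. Kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(h)
}

# Small string hash for provenance headers (djb2-style, hex-encoded).
hash_string <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
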