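# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is saved and restored).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic uniform deviates in [0, 1) from a 32-bit multiplicative
# congruential generator (x <- 69069 x + 1 mod 2^32). Used only for frozen
# descriptor sampling patterns, so patterns never depend on R's RNG.
lcg_uniform <- function(n, seed) {
  x <- as.double(seed) %% 2^32
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (69069 * x + 1) %% 2^32
    out[i] <- x / 2^32
  }
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-up, the package-wide rounding convention for intensities
round_half_up <- function(x) floor(x + 0.5)

# coefficient of variation; a series with zero spread has CV 0 by convention
coef_variation <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  s / mean(x)
}

# (max - min) / max, the drop of a positive series relative to its best value
relative_range <- function(x) {
  mx <- max(x)
  if (mx == 0) return(0)
  (mx - min(x)) / mx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
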