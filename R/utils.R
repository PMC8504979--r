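# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed.  Allows e.g. the
# number of bootstrap resamples to change without reshuffling earlier
# resamples, and makes per-individual imputation independent of the order in
# which individuals are processed.  Kept strictly below 2^31 - 1.
substream_seed <- function(master, i) {
  master <- as.double(master %% 2147483647L)
  # two rounds of a multiplicative congruential mix, in double precision
  # (exact for values < 2^53)
  s <- (master * 48271 + i * 16807 + 1) %% 2147483647
  s <- (s * 69621) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half away from zero (the convention used for reported edge
# probabilities; base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
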