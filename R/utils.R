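# Internal helpers: seeded RNG scopes and deterministic per-label seeds.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. A NULL seed evaluates code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit seed derived from a base seed and a character label, so each
# simulated cell draws from its own stream regardless of generation order.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647L
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

# Multiplicative lognormal factors with unit mean and coefficient of
# variation `cv` (cv = 0 gives exactly 1).
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
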