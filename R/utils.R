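# internal helpers

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps library functions from perturbing
# user-level reproducibility.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up for copy numbers (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# Poisson deviance: 2 * sum[ y*log(y/mu) - (y - mu) ], y*log(y) := 0 at y = 0
poisson_deviance <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(t1 - (y - mu))
}

poisson_loglik <- function(y, mu) {
  sum(stats::dpois(y, mu, log = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
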