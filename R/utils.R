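# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards: every stochastic component of the
# pipeline draws from its own deterministic stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# glmnet refuses single-column designs; pad with an all-zero dummy column
# (its coefficient is identically zero, so fits are unaffected)
pad_for_glmnet <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `..pad..` = 0)
}
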