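# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a base seed (kept below 2^31).
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# Scale rows of x from a box [lower, upper] to the unit cube, and back.
scale_to_unit <- function(x, lower, upper) {
  x <- rbind(x)
  sweep(sweep(x, 2L, lower, "-"), 2L, upper - lower, "/")
}

scale_from_unit <- function(u, lower, upper) {
  u <- rbind(u)
  sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
}
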