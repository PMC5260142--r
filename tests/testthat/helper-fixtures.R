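# Shared fixtures built in code.

# Draw y from a Gaussian process with the Gaussian kernel at known theta.
gp_sample <- function(x, theta, seed, nugget = 1e-10) {
  set.seed(seed)
  if (length(theta) == 1L) {
    S <- theta * as.matrix(dist(x))^2
  } else {
    S <- 0
    for (l in seq_len(ncol(x))) S <- S + theta[l] * outer(x[, l], x[, l], "-")^2
  }
  R <- exp(-S) + diag(nugget, nrow(x))
  drop(t(chol(R)) %*% rnorm(nrow(x)))
}

# Branin test function rescaled to the unit square (global minimum ~0.397887).
branin_unit <- function(u) {
  u <- as.numeric(u)
  x1 <- 15 * u[1L] - 5
  x2 <- 15 * u[2L]
  b <- 5.1 / (4 * pi^2)
  (x2 - b * x1^2 + (5 / pi) * x1 - 6)^2 + 10 * (1 - 1 / (8 * pi)) * cos(x1) + 10
}

# A random in-box stent design (rows of a seeded uniform draw).
random_stent_designs <- function(n, seed) {
  space <- stent_design_space()
  set.seed(seed)
  u <- matrix(runif(n * 7), ncol = 7)
  pts <- sweep(sweep(u, 2L, space$upper - space$lower, "*"), 2L, space$lower, "+")
  colnames(pts) <- space$names
  pts
}

# Brute-force scalarized objective of a sample table (independent of the
# package's scalarize/metric_bounds machinery).
brute_force_objective <- function(dr, rer, omega = 0.5) {
  a <- abs(dr)
  omega * (a - min(a)) / (max(a) - min(a)) +
    (1 - omega) * (rer - min(rer)) / (max(rer) - min(rer))
}
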