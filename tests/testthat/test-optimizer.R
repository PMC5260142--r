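test_that("the three-part convergence test is conjunctive and inclusive", {
  tol <- ego_tolerances(delta1 = 1e-3, delta2 = 1e-4, delta3 = 1e-4)
  # all residuals zero
  c0 <- check_convergence(ei = 0, f_k = 0.2, f_prev = 0.2, yhat_k = 0.2,
                          y_max = 1, y_min = 0, tol = tol)
  expect_true(c0$converged)
  # one criterion violated blocks convergence
  c1 <- check_convergence(ei = 10 * tol$delta1, f_k = 0.2, f_prev = 0.2,
                          yhat_k = 0.2, y_max = 1, y_min = 0, tol = tol)
  expect_false(c1$converged)
  expect_equal(unname(c1$satisfied), c(FALSE, TRUE, TRUE))
  # residuals exactly at the tolerances converge (inclusive)
  c2 <- check_convergence(ei = tol$delta1, f_k = 0.2 + tol$delta2, f_prev = 0.2,
                          yhat_k = 0.2 + tol$delta2 + tol$delta3,
                          y_max = 1, y_min = 0, tol = tol)
  expect_true(c2$converged)
  # degenerate archive range: absolute EI criterion with a warning
  expect_warning(
    cd <- check_convergence(ei = 5e-4, f_k = 0, f_prev = 0, yhat_k = 0,
                            y_max = 0.3, y_min = 0.3, tol = tol),
    "degenerate")
  expect_true(cd$converged)
  expect_error(ego_tolerances(delta1 = -1), "positive")
})

test_that("the adaptive loop locates a 1-D quadratic minimum", {
  sp <- design_space(0, 1, names = "x", levels = 5)
  fit <- ego(function(x) (x - 0.3)^2, sp, n_initial = 5,
             tolerances = ego_tolerances(max_iterations = 20), seed = 1)
  inc <- incumbent(fit)
  # dense-grid oracle
  grid <- seq(0, 1, length.out = 1e4)
  x_star <- grid[which.min((grid - 0.3)^2)]
  expect_lt(abs(inc$x - x_star), 0.05)
})

test_that("runs are reproducible and the archive grows by one per iteration", {
  sp <- design_space(c(0, 0), c(1, 1), levels = 3)
  f <- function(x) branin_unit(x)
  tol <- ego_tolerances(max_iterations = 6)
  a <- ego(f, sp, n_initial = 8, tolerances = tol, seed = 42, n_starts_ei = 16)
  b <- ego(f, sp, n_initial = 8, tolerances = tol, seed = 42, n_starts_ei = 16)
  expect_identical(a$archive, b$archive)
  expect_identical(a$trace, b$trace)
  # archive growth and budget safety
  infill <- a$archive[a$archive$iteration > 0, ]
  expect_equal(nrow(infill), max(a$archive$iteration))
  expect_equal(as.numeric(table(infill$iteration)),
               rep(1, max(a$archive$iteration)))
  expect_lte(nrow(a$archive) + length(a$failures), 8 + tol$max_iterations)
})

test_that("evaluator failures are recorded and skipped", {
  sp <- design_space(0, 1, names = "x", levels = 8)
  f <- function(x) {
    if (x > 0.45 && x < 0.55) stop("solver diverged")
    (x - 0.3)^2
  }
  fit <- ego(f, sp, n_initial = 6,
             tolerances = ego_tolerances(max_iterations = 15), seed = 3)
  # any recorded failures carry the evaluator's message
  if (length(fit$failures)) {
    expect_true(all(vapply(fit$failures, function(z)
      grepl("solver diverged", z$message), logical(1))))
  }
  # progress despite burned budget: incumbent near the minimum
  expect_lt(abs(incumbent(fit)$x - 0.3), 0.2)
  expect_lte(nrow(fit$archive) + length(fit$failures) - 6, 15)
})

test_that("incumbent selection minimizes the scalarized objective with earliest tie-break", {
  t1 <- table1_samples()
  b <- metric_bounds(t1$DR_32ms, t1$RER)
  f <- scalarize(t1$DR_32ms, t1$RER, b, 0.5)
  # independent brute-force of the weighted normalized sum
  f_oracle <- brute_force_objective(t1$DR_32ms, t1$RER, 0.5)
  expect_equal(f, f_oracle)
  expect_equal(which.min(f), which.min(f_oracle))
  # tie-break: earliest evaluation wins
  fake <- structure(list(archive = data.frame(x = c(1, 2, 3),
                                              objective = c(0.5, 0.2, 0.2))),
                    class = "ego")
  expect_equal(incumbent(fake)$x, 2)
})

test_that("the incumbent's raw metric pair is never dominated by an earlier one", {
  run <- optimize_stent(stent_sim_config(), n_initial = 12,
                        tolerances = ego_tolerances(max_iterations = 8),
                        seed = 21, n_starts_ei = 16)
  arch <- run$archive          # objectives under final bounds
  best_idx <- integer(0)
  cur <- Inf
  for (i in seq_len(nrow(arch))) {
    if (arch$objective[i] < cur) { cur <- arch$objective[i]; best_idx <- c(best_idx, i) }
  }
  inc_trace <- arch[best_idx, ]
  if (nrow(inc_trace) > 1) {
    for (i in 2:nrow(inc_trace)) {
      dominated <- abs(inc_trace$dr[i]) > abs(inc_trace$dr[i - 1]) &&
        inc_trace$rer[i] > inc_trace$rer[i - 1]
      expect_false(dominated)
    }
  }
})

test_that("the two-surrogate variant runs and improves on the reference design", {
  run <- optimize_stent(stent_sim_config(), n_initial = 12,
                        tolerances = ego_tolerances(max_iterations = 6),
                        seed = 5, n_starts_ei = 16, two_surrogates = TRUE)
  expect_s3_class(run, "ego")
  expect_gt(run$n_infill, 0)
  expect_true(all(is.finite(run$archive$objective)))
})
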