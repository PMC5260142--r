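#' Gaussian correlation function
#'
#' Spatial correlation between two points under the Gaussian kernel
#' \deqn{R(\theta, x^i, x^j) = \prod_l \exp[-\theta_l (x^i_l - x^j_l)^2].}
#' A scalar `theta` broadcasts across dimensions.
#'
#' @param theta Positive correlation decay parameter(s), scalar or length-m.
#' @param xi,xj Points of equal dimension.
#' @return Correlation in `(0, 1]`.
#' @export
gauss_corr <- function(theta, xi, xj) {
  if (any(theta <= 0) || any(!is.finite(theta))) {
    stop("'theta' must be positive", call. = FALSE)
  }
  xi <- as.numeric(xi); xj <- as.numeric(xj)
  if (length(xi) != length(xj)) {
    stop("points must have the same dimension", call. = FALSE)
  }
  if (length(theta) != 1L && length(theta) != length(xi)) {
    stop("'theta' must be scalar or one value per dimension", call. = FALSE)
  }
  exp(-sum(theta * (xi - xj)^2))
}

# Solve R a = b given the upper Cholesky factor U of R.
chol_solve <- function(U, b) {
  backsolve(U, backsolve(U, b, transpose = TRUE))
}

# Cholesky of R + nugget*I.  With escalate = TRUE the nugget climbs the
# ladder 1e-12, 1e-10, 1e-8 on failure; otherwise failure returns NULL.
# Mixing nugget levels inside one likelihood surface creates a spurious
# minimum at tiny theta (a singular R "rescued" by regularization shrinks
# |R|^(1/n) faster than sigma2 grows), so the theta search must evaluate
# every theta at one fixed nugget and only escalate between whole searches.
chol_with_nugget <- function(R, nugget = 0, escalate = TRUE) {
  ladder <- if (escalate) {
    l <- unique(c(nugget, 1e-12, 1e-10, 1e-8))
    l[l >= nugget]
  } else {
    nugget
  }
  n <- nrow(R)
  for (nug in ladder) {
    U <- tryCatch(chol(R + diag(nug, n)), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, nugget = nug))
  }
  NULL
}

# Squared-distance structure of scaled training inputs: for scalar theta a
# single matrix of squared Euclidean distances; for per-dimension theta one
# matrix per dimension.
sqdist_parts <- function(u, per_dim) {
  if (per_dim) {
    lapply(seq_len(ncol(u)), function(l) outer(u[, l], u[, l], "-")^2)
  } else {
    as.matrix(stats::dist(u))^2
  }
}

corr_matrix <- function(parts, theta, per_dim) {
  if (per_dim) {
    S <- 0
    for (l in seq_along(parts)) S <- S + theta[l] * parts[[l]]
    exp(-S)
  } else {
    exp(-theta * parts)
  }
}

#' Fit an ordinary Kriging (stochastic-process) surrogate
#'
#' Models the response as a constant trend plus a zero-mean stationary
#' Gaussian process with the Gaussian correlation kernel ([gauss_corr()]):
#' \deqn{y(x) = \beta + z(x), \quad \mathrm{corr}[z(x^i), z(x^j)] =
#'   \prod_l \exp[-\theta_l (x^i_l - x^j_l)^2].}
#' Given \eqn{\theta}, the generalized-least-squares estimates are
#' \deqn{\hat\beta = \frac{f^T R^{-1} y}{f^T R^{-1} f}, \qquad
#'   \hat\sigma^2 = \frac{(y - f\hat\beta)^T R^{-1} (y - f\hat\beta)}{n},}
#' and \eqn{\hat\theta} minimizes the concentrated-likelihood criterion
#' \eqn{\psi(\theta) = |R|^{1/n}\,\hat\sigma^2(\theta)} by seeded multistart
#' bounded search in \eqn{\log\theta} space.  Inputs are scaled to the unit
#' cube internally (so `theta` lives in scaled coordinates); the scaling
#' bounds are kept on the object and predictions accept original-space
#' points.  A diagonal nugget is escalated through `0, 1e-12, 1e-10, 1e-8`
#' if the correlation matrix fails to factorize.
#'
#' @param x Numeric matrix of training inputs (`n x m`), or a vector for
#'   `m = 1`.
#' @param y Numeric response vector of length `n`.
#' @param bounds Optional [design_space()] or `list(lower, upper)` giving the
#'   scaling box; defaults to the per-column data range.
#' @param theta Optional fixed correlation parameter(s); skips the search.
#' @param theta_bounds Search box for `theta` (scaled coordinates), default
#'   `c(1e-3, 1e2)`.
#' @param per_dim_theta If `TRUE`, fit one `theta` per dimension; the default
#'   (`FALSE`) uses a single shared `theta`.
#' @param nugget Initial diagonal regularization of the correlation matrix.
#' @param n_starts Number of multistart points for the `theta` search.
#' @param seed Seed for the multistart draw.
#' @param dedup_tol Minimum allowed pairwise distance between scaled training
#'   points; closer duplicates are an error.
#' @return An object of class `kriging`; see [predict.kriging()],
#'   [expected_improvement()], [residuals.kriging()], [simulate.kriging()].
#' @examples
#' x <- matrix(runif(30), ncol = 2)
#' y <- sin(4 * x[, 1]) + x[, 2]^2
#' fit <- kriging(x, y, seed = 1)
#' predict(fit, c(0.5, 0.5), se.fit = TRUE)
#' @export
kriging <- function(x, y, bounds = NULL, theta = NULL,
                    theta_bounds = c(1e-3, 1e2), per_dim_theta = FALSE,
                    nugget = 0, n_starts = 10, seed = NULL,
                    dedup_tol = 1e-10) {
  x <- rbind(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  m <- ncol(x)
  if (length(y) != n) stop("'x' and 'y' sizes disagree", call. = FALSE)
  if (n < 1L) stop("at least one training point is required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("training data must be finite", call. = FALSE)
  }

  if (is.null(bounds)) {
    lower <- apply(x, 2L, min)
    upper <- apply(x, 2L, max)
    w <- upper - lower
    upper[w == 0] <- lower[w == 0] + 1      # degenerate column: unit width
  } else if (inherits(bounds, "design_space")) {
    lower <- bounds$lower; upper <- bounds$upper
  } else {
    lower <- as.numeric(bounds$lower); upper <- as.numeric(bounds$upper)
  }
  if (length(lower) != m || length(upper) != m || any(upper <= lower)) {
    stop("invalid scaling bounds", call. = FALSE)
  }

  u <- scale_to_unit(x, lower, upper)
  obj <- structure(
    list(x = x, u = u, y = y, lower = lower, upper = upper,
         per_dim_theta = per_dim_theta, call = match.call()),
    class = "kriging"
  )

  # Degenerate cases: single point, or zero response variance.
  if (n == 1L || stats::sd(y) == 0) {
    if (n > 1L) {
      warning("constant response: surrogate degenerates to its trend (sigma2 = 0)",
              call. = FALSE)
      d <- min(stats::dist(u))
      if (d < dedup_tol) stop("duplicate training points", call. = FALSE)
    }
    obj$beta <- y[1L]
    obj$sigma2 <- 0
    obj$theta <- if (is.null(theta)) rep(1, if (per_dim_theta) m else 1L) else theta
    obj$nugget <- nugget
    obj$degenerate <- TRUE
    return(obj)
  }
  if (min(stats::dist(u)) < dedup_tol) {
    stop("duplicate training points after unit-cube scaling; deduplicate inputs",
         call. = FALSE)
  }

  parts <- sqdist_parts(u, per_dim_theta)
  n_theta <- if (per_dim_theta) m else 1L
  f <- rep(1, n)

  # log psi(theta) = log|R|/n + log sigma2(theta), profiled over beta, sigma2;
  # evaluated at a fixed nugget so psi values are comparable across theta.
  # Correlation matrices conditioned worse than ~1e14 (Cholesky pivot ratio
  # below 1e-7) are rejected: psi keeps decreasing into that region for some
  # data, but the resulting "fit" is numerical noise that cannot interpolate.
  eval_lpsi <- function(ltheta, nug) {
    R <- corr_matrix(parts, exp(ltheta), per_dim_theta)
    ch <- chol_with_nugget(R, nug, escalate = FALSE)
    if (is.null(ch)) return(1e10)
    dg <- diag(ch$U)
    if (min(dg) / max(dg) < 1e-6) return(1e10)
    logdet <- 2 * sum(log(diag(ch$U)))
    Ri_y <- chol_solve(ch$U, y)
    Ri_f <- chol_solve(ch$U, f)
    beta <- sum(Ri_y) / sum(Ri_f)
    res <- y - beta
    s2 <- sum(res * (Ri_y - beta * Ri_f)) / n
    if (!is.finite(s2) || s2 <= 0) return(1e10)
    logdet / n + log(s2)
  }

  search_theta <- function(lb, ub) {
    starts <- with_seed(seed, {
      s0 <- matrix(stats::runif((n_starts - 1L) * n_theta, lb, ub),
                   ncol = n_theta)
      rbind(rep(0.5 * (lb + ub), n_theta), s0)
    })
    best <- NULL
    for (nug in unique(c(nugget, 1e-12, 1e-10, 1e-8))) {
      if (nug < nugget) next
      for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
          stats::optim(starts[i, ], eval_lpsi, nug = nug, method = "L-BFGS-B",
                       lower = rep(lb, n_theta), upper = rep(ub, n_theta),
                       control = list(maxit = 200)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
      }
      if (!is.null(best) && best$value < 1e9) break  # feasible at this nugget
    }
    if (is.null(best) || best$value >= 1e9) {
      stop("theta search failed at every start", call. = FALSE)
    }
    exp(best$par)
  }

  lb <- log(theta_bounds[1L]); ub <- log(theta_bounds[2L])
  y_scale <- max(abs(y))
  for (attempt in 1:8) {
    if (is.null(theta)) {
      theta_hat <- search_theta(lb, ub)
    } else {
      theta_hat <- rep_len(theta, n_theta)
      if (any(theta_hat <= 0)) stop("'theta' must be positive", call. = FALSE)
    }

    R <- corr_matrix(parts, theta_hat, per_dim_theta)
    ch <- chol_with_nugget(R, nugget)
    if (is.null(ch)) {
      stop("correlation matrix singular even at maximum nugget; deduplicate points",
           call. = FALSE)
    }
    Ri_y <- chol_solve(ch$U, y)
    Ri_f <- chol_solve(ch$U, f)
    fRf <- sum(Ri_f)
    beta <- sum(Ri_y) / fRf
    res <- y - beta
    gamma <- Ri_y - beta * Ri_f
    sigma2 <- max(sum(res * gamma) / n, 0)
    logdet <- 2 * sum(log(diag(ch$U)))

    # numerical safeguard: the model must reproduce its own training data
    # through the same arithmetic predict() uses (a backward-stable solve
    # masks forward error when R is near-singular and gamma is huge); if
    # conditioning at the selected theta breaks interpolation, exclude the
    # offending low-theta region and search again
    if (per_dim_theta) {
      S <- 0
      for (l in seq_len(m)) S <- S + theta_hat[l] * outer(u[, l], u[, l], "-")^2
      R_fwd <- exp(-S)
    } else {
      S <- outer(rowSums(u^2), rowSums(u^2), "+") - 2 * tcrossprod(u)
      R_fwd <- exp(-theta_hat * pmax(S, 0))
    }
    interp_err <- max(abs(drop(crossprod(R_fwd, gamma)) + beta - y))
    if (is.null(theta) && interp_err > 1e-7 * y_scale && attempt < 8L &&
        min(theta_hat) < exp(ub)) {
      lb <- log(min(theta_hat)) + log(10)
      if (lb >= ub) lb <- ub - 1e-3
      next
    }
    break
  }
  if (interp_err > 1e-6 * y_scale) {
    warning(paste0("surrogate cannot reproduce its training responses to ",
                   "numerical precision; responses may be inconsistent ",
                   "(noisy) at near-duplicate inputs"), call. = FALSE)
  }

  obj$theta <- theta_hat
  obj$beta <- beta
  obj$sigma2 <- sigma2
  obj$nugget <- ch$nugget
  obj$U <- ch$U
  obj$gamma <- gamma
  obj$Ri_f <- Ri_f
  obj$fRf <- fRf
  obj$logdet <- logdet
  obj$psi <- exp(logdet / n) * sigma2
  obj$degenerate <- FALSE
  obj
}

# Concentrated-likelihood criterion psi(theta) = |R|^(1/n) sigma2(theta) of a
# fitted model re-evaluated at an arbitrary theta (diagnostics/tests).
kriging_psi <- function(object, theta) {
  stopifnot(inherits(object, "kriging"))
  parts <- sqdist_parts(object$u, object$per_dim_theta)
  n <- length(object$y)
  f <- rep(1, n)
  R <- corr_matrix(parts, theta, object$per_dim_theta)
  ch <- chol_with_nugget(R, object$nugget)
  if (is.null(ch)) return(Inf)
  Ri_y <- chol_solve(ch$U, object$y)
  Ri_f <- chol_solve(ch$U, f)
  beta <- sum(Ri_y) / sum(Ri_f)
  res <- object$y - beta
  s2 <- sum(res * (Ri_y - beta * Ri_f)) / n
  exp(2 * sum(log(diag(ch$U))) / n) * s2
}

# Correlation vectors r(x*) between scaled prediction points (rows of un)
# and the training set: n x n_new matrix.
cross_corr <- function(object, un) {
  u <- object$u
  theta <- object$theta
  if (object$per_dim_theta) {
    S <- 0
    for (l in seq_len(ncol(u))) {
      S <- S + theta[l] * outer(u[, l], un[, l], "-")^2
    }
    exp(-S)
  } else {
    S <- outer(rowSums(u^2), rowSums(un^2), "+") - 2 * u %*% t(un)
    exp(-theta * pmax(S, 0))
  }
}

# Scale newdata into the model's unit cube, accepting vectors or matrices.
prep_newdata <- function(object, newdata, scaled = FALSE) {
  xn <- rbind(newdata)
  if (ncol(xn) != ncol(object$x)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(xn), ncol(object$x)), call. = FALSE)
  }
  if (any(!is.finite(xn))) stop("newdata must be finite", call. = FALSE)
  if (scaled) xn else scale_to_unit(xn, object$lower, object$upper)
}

#' Predict from a Kriging surrogate
#'
#' Best linear unbiased prediction
#' \eqn{\hat y(x^*) = \hat\beta + r(x^*)^T \gamma} with
#' \eqn{\gamma = R^{-1}(y - f\hat\beta)}, and its mean squared error
#' \deqn{\sigma^2(x^*) = \hat\sigma^2\left[1 - r^T R^{-1} r +
#'   \frac{(1 - f^T R^{-1} r)^2}{f^T R^{-1} f}\right]}
#' (clamped at 0 if numerically negative).  The predictor interpolates: at a
#' training point the mean equals the observed response and the MSE is at
#' nugget scale.
#'
#' @param object A fitted [kriging()] model.
#' @param newdata Point(s) to predict at: a vector (one point) or a matrix
#'   with one row per point, in original coordinates unless `scaled = TRUE`.
#' @param se.fit If `TRUE`, also return the predictor MSE and its root.
#' @param scaled Set `TRUE` when `newdata` is already unit-cube scaled.
#' @param ... Unused.
#' @return A numeric vector of predictions, or when `se.fit = TRUE` a list
#'   with elements `fit`, `mse` and `se.fit`.
#' @export
predict.kriging <- function(object, newdata, se.fit = FALSE, scaled = FALSE, ...) {
  un <- prep_newdata(object, newdata, scaled)
  if (isTRUE(object$degenerate)) {
    mu <- rep(object$beta, nrow(un))
    if (!se.fit) return(mu)
    return(list(fit = mu, mse = rep(0, nrow(un)), se.fit = rep(0, nrow(un))))
  }
  r <- cross_corr(object, un)                      # n x n_new
  mu <- object$beta + drop(crossprod(r, object$gamma))
  if (!se.fit) return(mu)
  Ri_r <- chol_solve(object$U, r)
  h <- 1 - colSums(object$Ri_f * r)                # 1 - f' R^-1 r
  mse <- object$sigma2 * (1 - colSums(r * Ri_r) + h^2 / object$fRf)
  if (any(mse < -1e-6 * max(object$sigma2, 1e-300))) {
    warning("negative predictor MSE clamped to 0", call. = FALSE)
  }
  mse <- pmax(mse, 0)
  list(fit = mu, mse = mse, se.fit = sqrt(mse))
}

#' Expected improvement of candidate points
#'
#' The one-step improvement over the incumbent `y_min` expected under the
#' surrogate's Gaussian predictive distribution:
#' \deqn{EI(x) = \sigma(x)\left[u\,\Phi(u) + \phi(u)\right], \qquad
#'   u = \frac{y_{min} - \hat y(x)}{\sigma(x)},}
#' and `EI = 0` where the predictive deviation vanishes (within
#' `1e-12 * sigma2` of zero), e.g. at training points.
#'
#' @param object A fitted [kriging()] model.
#' @param newdata Candidate point(s) as in [predict.kriging()].
#' @param y_min Current best (minimal) objective value; defaults to the
#'   training minimum.
#' @param scaled Set `TRUE` when `newdata` is already unit-cube scaled.
#' @return Non-negative expected improvement value(s).
#' @export
expected_improvement <- function(object, newdata, y_min = min(object$y),
                                 scaled = FALSE) {
  stopifnot(inherits(object, "kriging"))
  if (!is.finite(y_min)) stop("'y_min' must be finite", call. = FALSE)
  p <- predict(object, newdata, se.fit = TRUE, scaled = scaled)
  ei <- numeric(length(p$fit))
  live <- p$mse > 1e-12 * max(object$sigma2, 0)
  if (any(live)) {
    ei[live] <- ei_value(p$fit[live], sqrt(p$mse[live]), y_min)
  }
  pmax(ei, 0)
}

# Closed-form expected improvement for a Gaussian predictive distribution
# N(mu, sd^2) against incumbent y_min; the sd = 0 branch is exactly 0.
ei_value <- function(mu, sd, y_min) {
  ei <- numeric(length(mu))
  live <- sd > 0
  if (any(live)) {
    u <- (y_min - mu[live]) / sd[live]
    ei[live] <- sd[live] * (u * stats::pnorm(u) + stats::dnorm(u))
  }
  pmax(ei, 0)
}

#' Maximize expected improvement over a design box
#'
#' Seeded multistart bounded local search (`L-BFGS-B`) of [expected_improvement()]
#' over a [design_space()] box.  Starts are the best training point plus
#' `n_starts - 1` seeded uniform points.  When EI is everywhere negligible
#' (e.g. a degenerate surrogate) the best start is returned with
#' `degenerate = TRUE`.
#'
#' @param object A fitted [kriging()] model.
#' @param space The [design_space()] to search (original coordinates).
#' @param y_min Incumbent objective value; defaults to the training minimum.
#' @param seed Seed for the start draw.
#' @param n_starts Total number of starts (default 64).
#' @return A list with `par` (named candidate point), `ei`, `degenerate`,
#'   and `candidates` — a matrix of all local optima found, ordered by
#'   decreasing EI (useful as fallbacks when an evaluation fails).
#' @export
maximize_ei <- function(object, space, y_min = min(object$y), seed = NULL,
                        n_starts = 64) {
  stopifnot(inherits(object, "kriging"), inherits(space, "design_space"))
  m <- space_dim(space)
  x_best <- object$x[which.min(object$y), , drop = FALSE]
  starts <- with_seed(seed, {
    s0 <- matrix(stats::runif((n_starts - 1L) * m), ncol = m)
    rbind(scale_to_unit(x_best, space$lower, space$upper),
          s0)
  })
  neg_ei <- function(uu) {
    -expected_improvement(object,
                          scale_from_unit(uu, space$lower, space$upper),
                          y_min = y_min)
  }
  pars <- matrix(NA_real_, nrow(starts), m)
  eis <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], 0), 1), neg_ei, method = "L-BFGS-B",
                   lower = rep(0, m), upper = rep(1, m),
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit)) {
      pars[i, ] <- pmin(pmax(starts[i, ], 0), 1)
      eis[i] <- -neg_ei(starts[i, , drop = FALSE])
    } else {
      pars[i, ] <- fit$par
      eis[i] <- -fit$value
    }
  }
  ord <- order(eis, decreasing = TRUE)
  cand <- scale_from_unit(pars[ord, , drop = FALSE], space$lower, space$upper)
  colnames(cand) <- space$names
  degenerate <- eis[ord[1L]] <= 1e-300
  list(par = stats::setNames(cand[1L, ], space$names), ei = eis[ord[1L]],
       degenerate = degenerate, candidates = cand, ei_all = eis[ord])
}

#' @export
print.kriging <- function(x, ...) {
  cat(sprintf("Ordinary Kriging surrogate: n = %d points, m = %d variables\n",
              length(x$y), ncol(x$x)))
  cat(sprintf("  theta  = %s%s\n", paste(signif(x$theta, 5), collapse = " "),
              if (x$per_dim_theta) " (per dimension)" else ""))
  cat(sprintf("  beta   = %.6g   sigma2 = %.6g   nugget = %g\n",
              x$beta, x$sigma2, x$nugget))
  if (isTRUE(x$degenerate)) cat("  (degenerate: constant response)\n")
  invisible(x)
}

#' @export
coef.kriging <- function(object, ...) {
  th <- object$theta
  names(th) <- if (length(th) == 1L) "theta" else paste0("theta", seq_along(th))
  c(beta = object$beta, sigma2 = object$sigma2, th)
}

#' Leave-one-out residuals of a Kriging surrogate
#'
#' The model interpolates, so ordinary residuals are identically zero; the
#' informative residual is leave-one-out: `y_i` minus the prediction of a
#' model refitted without point `i` (at the same `theta`), computed in closed
#' form from the bordered correlation system.
#'
#' @param object A fitted [kriging()] model.
#' @param ... Unused.
#' @return Numeric vector of LOO residuals.
#' @export
residuals.kriging <- function(object, ...) {
  n <- length(object$y)
  if (isTRUE(object$degenerate) || n < 3L) return(rep(0, n))
  R <- crossprod(object$U)                       # R + nugget I
  K <- rbind(cbind(R, rep(1, n)), c(rep(1, n), 0))
  B <- solve(K)
  a <- drop(B %*% c(object$y, 0))
  unname(a[seq_len(n)] / diag(B)[seq_len(n)])
}

#' @export
fitted.kriging <- function(object, ...) {
  object$y - residuals(object)
}

#' @export
summary.kriging <- function(object, ...) {
  r <- residuals(object)
  out <- list(n = length(object$y), m = ncol(object$x),
              coef = coef(object), nugget = object$nugget,
              psi = object$psi, loo_rmse = sqrt(mean(r^2)),
              degenerate = isTRUE(object$degenerate))
  class(out) <- "summary.kriging"
  out
}

#' @export
print.summary.kriging <- function(x, ...) {
  cat(sprintf("Ordinary Kriging surrogate (n = %d, m = %d)\n", x$n, x$m))
  print(signif(x$coef, 6))
  cat(sprintf("nugget: %g\n", x$nugget))
  if (!x$degenerate) {
    cat(sprintf("concentrated criterion psi(theta): %.6g\n", x$psi))
    cat(sprintf("leave-one-out RMSE: %.6g\n", x$loo_rmse))
  } else {
    cat("degenerate model (constant response)\n")
  }
  invisible(x)
}

#' Draw conditional Gaussian-process sample paths
#'
#' Samples from the surrogate's predictive distribution jointly at a set of
#' points (conditional on the training data), using the full predictive
#' covariance of the constant-trend model.
#'
#' @param object A fitted [kriging()] model.
#' @param nsim Number of sample paths.
#' @param seed Optional seed.
#' @param newdata Points to sample at (one row per point).
#' @param scaled Set `TRUE` when `newdata` is already unit-cube scaled.
#' @param ... Unused.
#' @return A matrix with one row per point in `newdata` and `nsim` columns.
#' @export
simulate.kriging <- function(object, nsim = 1, seed = NULL, newdata,
                             scaled = FALSE, ...) {
  un <- prep_newdata(object, newdata, scaled)
  k <- nrow(un)
  mu <- predict(object, un, scaled = TRUE)
  if (isTRUE(object$degenerate) || object$sigma2 == 0) {
    return(matrix(mu, nrow = k, ncol = nsim))
  }
  r <- cross_corr(object, un)
  Ri_r <- chol_solve(object$U, r)
  parts <- sqdist_parts(un, object$per_dim_theta)
  Rnn <- corr_matrix(parts, object$theta, object$per_dim_theta)
  h <- 1 - colSums(object$Ri_f * r)
  C <- object$sigma2 * (Rnn - crossprod(r, Ri_r) + tcrossprod(h) / object$fRf)
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), k)
  with_seed(seed, {
    z <- matrix(stats::rnorm(k * nsim), k, nsim)
    mu + A %*% z
  })
}

#' Diagnostic plot of a Kriging surrogate
#'
#' For one-dimensional models, the predictive mean with a 95% band over the
#' input range plus the training points; otherwise leave-one-out predictions
#' against observed responses.
#'
#' @param x A fitted [kriging()] model.
#' @param n_grid Grid resolution for the 1-D curve.
#' @param ... Passed to the underlying plot call.
#' @export
plot.kriging <- function(x, n_grid = 200, ...) {
  if (ncol(x$x) == 1L) {
    g <- seq(min(x$x), max(x$x), length.out = n_grid)
    p <- predict(x, matrix(g, ncol = 1L), se.fit = TRUE)
    plot(g, p$fit, type = "l", xlab = "x", ylab = "prediction", ...)
    graphics::lines(g, p$fit + 1.96 * p$se.fit, lty = 2)
    graphics::lines(g, p$fit - 1.96 * p$se.fit, lty = 2)
    graphics::points(x$x, x$y, pch = 19)
  } else {
    f <- fitted(x)
    plot(x$y, f, xlab = "observed", ylab = "leave-one-out prediction", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
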