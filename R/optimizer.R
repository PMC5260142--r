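#' Convergence tolerances for the adaptive optimization loop
#'
#' @param delta1 Relative expected-improvement threshold: the loop requires
#'   `EI_k / (Y_max - Y_min) <= delta1`.
#' @param delta2 Objective-change threshold `|f_k - f_{k-1}| <= delta2`.
#' @param delta3 Surrogate-accuracy threshold `|f_k - yhat_k| <= delta3`.
#' @param max_iterations Infill evaluation budget.
#' @return A list of class `ego_tolerances`.
#' @export
ego_tolerances <- function(delta1 = 1e-3, delta2 = 1e-4, delta3 = 1e-4,
                           max_iterations = 50L) {
  if (any(c(delta1, delta2, delta3) <= 0)) {
    stop("convergence tolerances must be positive", call. = FALSE)
  }
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("'max_iterations' must be >= 1", call. = FALSE)
  structure(list(delta1 = delta1, delta2 = delta2, delta3 = delta3,
                 max_iterations = max_iterations),
            class = "ego_tolerances")
}

#' Three-part convergence test of the adaptive loop
#'
#' The loop stops when all three criteria hold (conjunction; inclusive
#' comparisons): the expected improvement relative to the archive's objective
#' range is below `delta1`; the objective changed by at most `delta2` between
#' consecutive infill points; and the surrogate predicted the last infill's
#' true objective to within `delta3`.  When the archive's objective range is
#' degenerate (`y_max = y_min`) the first criterion falls back to absolute
#' `EI <= delta1` with a warning.
#'
#' @param ei Expected improvement of the current infill candidate.
#' @param f_k,f_prev Objective values at the current and previous infill.
#' @param yhat_k Surrogate prediction at the current infill.
#' @param y_max,y_min Objective extrema over the sample archive.
#' @param tol An [ego_tolerances()] object.
#' @return A list with `converged`, per-criterion `residuals`
#'   (`ei_rel`, `delta_f`, `pred_gap`) and the logical vector `satisfied`.
#' @export
check_convergence <- function(ei, f_k, f_prev, yhat_k, y_max, y_min,
                              tol = ego_tolerances()) {
  stopifnot(inherits(tol, "ego_tolerances"))
  rng <- y_max - y_min
  if (rng <= 0) {
    warning("degenerate archive objective range; using absolute EI criterion",
            call. = FALSE)
    ei_rel <- ei
  } else {
    ei_rel <- ei / rng
  }
  residuals <- c(ei_rel = as.numeric(ei_rel)[1L],
                 delta_f = as.numeric(abs(f_k - f_prev))[1L],
                 pred_gap = as.numeric(abs(f_k - yhat_k))[1L])
  satisfied <- residuals <= c(tol$delta1, tol$delta2, tol$delta3)
  list(converged = all(satisfied), residuals = residuals, satisfied = satisfied)
}

# Evaluate one design through a black-box evaluator, classifying the result.
# Returns list(ok, dr, dr_post, rer, pressure, value, expansion, message).
eval_design <- function(evaluator, design) {
  out <- tryCatch(evaluator(design), error = function(e) e)
  if (inherits(out, "error")) {
    return(list(ok = FALSE, message = conditionMessage(out)))
  }
  if (inherits(out, "expansion_result")) {
    met <- compute_metrics(out)
    return(list(ok = TRUE, dr = met$dr, dr_post = met$dr_post, rer = met$rer,
                pressure = out$pressure, value = NA_real_, expansion = out))
  }
  if (is.numeric(out) && length(out) == 1L && is.finite(out)) {
    return(list(ok = TRUE, dr = NA_real_, dr_post = NA_real_, rer = NA_real_,
                pressure = NA_real_, value = as.numeric(out), expansion = NULL))
  }
  list(ok = FALSE,
       message = "evaluator must return an expansion_result or a finite scalar")
}

# Scalarized objectives of the archive under freshly recomputed bounds.
archive_objectives <- function(archive, omega, metric_mode) {
  if (!metric_mode) {
    return(list(objective = archive$value, bounds = NULL))
  }
  bounds <- metric_bounds(archive$dr, archive$rer)
  obj <- withCallingHandlers(
    scalarize(archive$dr, archive$rer, bounds, omega),
    warning = function(w) invokeRestart("muffleWarning"))
  list(objective = obj, bounds = bounds)
}

#' Adaptive Kriging-surrogate optimization (EGO loop)
#'
#' Runs the full adaptive loop: (1) an initial MRG sample over the design
#' box; (2) black-box evaluation of every sample; (3) the sample with the
#' minimal scalarized objective as incumbent; then repeatedly (4) refit the
#' Kriging surrogate to the objective, (5) locate the expected-improvement
#' maximum, (6) evaluate it and compare with the surrogate's prediction, and
#' (7) test convergence and add the point to the archive.  Because the
#' objective normalizes metrics by their archive extrema, all archive
#' objectives are re-scalarized against refreshed bounds before every refit.
#'
#' Two evaluator contracts are supported: a stent-type evaluator returning an
#' [expansion_result()] (objectives are the weighted normalized sum of
#' `|DR|` and `RER`), or a plain scalar objective function (used directly,
#' no normalization) for benchmarking the loop on test functions.
#'
#' @param evaluator A function of one design vector returning an
#'   [expansion_result()] or a finite scalar.  Errors raised by the
#'   evaluator are recorded, the candidate is skipped, and the loop proceeds
#'   with the next-best EI candidate.
#' @param space The [design_space()] to optimize over.
#' @param n_initial Initial MRG sample size.
#' @param omega Dogboning weight of the scalarized objective, in `(0, 1)`.
#' @param tolerances An [ego_tolerances()] object.
#' @param seed Integer seed; fixes the DOE, the theta search and the EI
#'   multistarts, making whole runs reproducible.
#' @param include Optional matrix (or single vector) of extra designs
#'   evaluated and added to the initial archive, e.g. a reference design.
#' @param n_starts_ei Multistart count for the EI maximization.
#' @param per_dim_theta Passed to [kriging()].
#' @param two_surrogates If `TRUE` (stent-type evaluators only), fit separate
#'   surrogates to `|DR|` and `RER` and scalarize at prediction time instead
#'   of fitting one surrogate to the scalarized objective (the default).
#' @param verbose Print one line per iteration.
#' @return An object of class `ego`: archive data frame (designs, metrics,
#'   objectives under final bounds, provenance), iteration trace with
#'   convergence residuals, final surrogate, convergence status and seeds.
#' @seealso [incumbent()], [optimize_stent()], [write_run_report()].
#' @examples
#' sp <- design_space(0, 1, names = "x", levels = 5)
#' fit <- ego(function(x) (x - 0.3)^2, sp, n_initial = 5,
#'            tolerances = ego_tolerances(max_iterations = 10), seed = 1)
#' incumbent(fit)
#' @export
ego <- function(evaluator, space, n_initial = 30L, omega = 0.5,
                tolerances = ego_tolerances(), seed = NULL, include = NULL,
                n_starts_ei = 64L, per_dim_theta = FALSE,
                two_surrogates = FALSE, verbose = FALSE) {
  stopifnot(inherits(space, "design_space"), inherits(tolerances, "ego_tolerances"))
  m <- space_dim(space)

  # Steps 1-2: initial DOE and evaluation
  doe <- mrg_sample(space, n_initial, seed = child_seed(seed, 1L))
  init_pts <- doe$points
  if (!is.null(include)) {
    include <- rbind(include)
    if (ncol(include) != m) stop("'include' designs have the wrong dimension",
                                 call. = FALSE)
    init_pts <- rbind(include, init_pts)
  }
  n_inc <- if (is.null(include)) 0L else nrow(include)

  failures <- list()
  rows <- list()
  expansions <- list()
  metric_mode <- NA
  for (i in seq_len(nrow(init_pts))) {
    res <- eval_design(evaluator, stats::setNames(init_pts[i, ], space$names))
    prov <- if (i <= n_inc) "seed-design" else "initial-DOE"
    if (!res$ok) {
      failures[[length(failures) + 1L]] <-
        list(design = init_pts[i, ], iteration = 0L, message = res$message)
      next
    }
    if (is.na(metric_mode)) metric_mode <- !is.null(res$expansion)
    rows[[length(rows) + 1L]] <-
      data.frame(rbind(init_pts[i, , drop = TRUE]), pressure = res$pressure,
                 dr = res$dr, dr_post = res$dr_post, rer = res$rer,
                 value = res$value, ei = NA_real_, yhat = NA_real_,
                 iteration = 0L, provenance = prov)
    expansions[[length(rows)]] <- res$expansion
  }
  if (length(rows) < 2L) {
    stop("fewer than 2 successful initial evaluations; cannot fit a surrogate",
         call. = FALSE)
  }
  archive <- do.call(rbind, rows)
  names(archive)[seq_len(m)] <- space$names

  trace <- list()
  converged <- FALSE
  fired <- c(ei_rel = FALSE, delta_f = FALSE, pred_gap = FALSE)
  f_prev <- NA_real_
  model <- NULL
  infill_calls <- 0L
  k <- 0L

  while (infill_calls < tolerances$max_iterations) {
    k <- k + 1L
    # D-O1: refresh bounds and re-scalarize the whole archive before refit
    sc <- archive_objectives(archive, omega, metric_mode)
    archive$objective <- sc$objective
    if (is.na(f_prev)) f_prev <- min(archive$objective)   # Step-3 incumbent

    X <- as.matrix(archive[, space$names, drop = FALSE])
    fit_seed <- child_seed(seed, 100L + k)
    if (two_surrogates && metric_mode) {
      sur <- fit_two_surrogates(X, archive, sc$bounds, omega, space,
                                per_dim_theta, fit_seed)
      model <- sur$model_dr       # reported model: the |DR| surrogate
      mx <- maximize_ei_scalarized(sur, space, min(archive$objective),
                                   seed = child_seed(seed, 200L + k),
                                   n_starts = n_starts_ei)
    } else {
      model <- kriging(X, archive$objective, bounds = space,
                       per_dim_theta = per_dim_theta, seed = fit_seed)
      mx <- maximize_ei(model, space, y_min = min(archive$objective),
                        seed = child_seed(seed, 200L + k),
                        n_starts = n_starts_ei)
    }

    # Steps 5-6: evaluate the EI-maximal candidate (falling back down the
    # candidate ranking if the evaluator fails), predict, compare
    res <- NULL; x_k <- NULL; ei_k <- NA_real_
    for (ci in seq_len(nrow(mx$candidates))) {
      if (infill_calls >= tolerances$max_iterations) break
      cand <- stats::setNames(mx$candidates[ci, ], space$names)
      infill_calls <- infill_calls + 1L
      r <- eval_design(evaluator, cand)
      if (r$ok) {
        res <- r; x_k <- cand
        ei_k <- if (ci == 1L) mx$ei else mx$ei_all[ci]
        break
      }
      failures[[length(failures) + 1L]] <-
        list(design = cand, iteration = k, message = r$message)
    }
    if (is.null(res)) break   # budget exhausted on failures

    yhat_k <- if (two_surrogates && metric_mode) {
      predict_scalarized(sur, rbind(x_k))$fit
    } else {
      predict(model, rbind(x_k))
    }
    f_k <- if (metric_mode) {
      withCallingHandlers(
        scalarize(res$dr, res$rer, sc$bounds, omega),
        warning = function(w) invokeRestart("muffleWarning"))
    } else {
      res$value
    }

    # Step 7: convergence on the current iteration, then archive the point
    conv <- check_convergence(ei_k, f_k, f_prev, yhat_k,
                              y_max = max(archive$objective),
                              y_min = min(archive$objective), tol = tolerances)
    new_row <- data.frame(rbind(x_k), pressure = res$pressure, dr = res$dr,
                          dr_post = res$dr_post, rer = res$rer,
                          value = res$value, ei = ei_k, yhat = yhat_k,
                          iteration = k, provenance = "infill",
                          objective = f_k)
    names(new_row)[seq_len(m)] <- space$names
    archive <- rbind(archive, new_row)
    expansions[[nrow(archive)]] <- res$expansion

    trace[[k]] <- data.frame(iteration = k, ei = ei_k,
                             ei_rel = conv$residuals[["ei_rel"]],
                             f_k = f_k, f_prev = f_prev, yhat = yhat_k,
                             delta_f = conv$residuals[["delta_f"]],
                             pred_gap = conv$residuals[["pred_gap"]],
                             converged = conv$converged)
    if (verbose) {
      message(sprintf(
        "iter %2d: EI %.3g (rel %.3g) f_k %.5f yhat %.5f |df| %.3g",
        k, ei_k, conv$residuals[["ei_rel"]], f_k, yhat_k,
        conv$residuals[["delta_f"]]))
    }
    f_prev <- f_k
    if (conv$converged) {
      converged <- TRUE
      fired <- conv$satisfied
      break
    }
  }

  # Final re-scalarization over the complete archive
  sc <- archive_objectives(archive, omega, metric_mode)
  archive$objective <- sc$objective
  rownames(archive) <- NULL

  structure(
    list(archive = archive, expansions = expansions, bounds = sc$bounds,
         trace = if (length(trace)) do.call(rbind, trace) else NULL,
         converged = converged, criteria_satisfied = fired,
         n_infill = if (is.null(archive$iteration)) 0L else max(archive$iteration),
         n_evaluations = nrow(archive) + length(failures),
         failures = failures, model = model, space = space,
         config = list(n_initial = n_initial, omega = omega,
                       tolerances = tolerances, seed = seed,
                       metric_mode = metric_mode,
                       two_surrogates = two_surrogates,
                       n_starts_ei = n_starts_ei)),
    class = "ego"
  )
}

# --- optional two-surrogate mode (separate |DR| and RER models) ------------

fit_two_surrogates <- function(X, archive, bounds, omega, space,
                               per_dim_theta, seed) {
  m_dr <- kriging(X, abs(archive$dr), bounds = space,
                  per_dim_theta = per_dim_theta, seed = seed)
  m_rer <- kriging(X, archive$rer, bounds = space,
                   per_dim_theta = per_dim_theta, seed = child_seed(seed, 7L))
  den_dr <- max(bounds$abs_dr_max - bounds$abs_dr_min, .Machine$double.eps)
  den_rer <- max(bounds$rer_max - bounds$rer_min, .Machine$double.eps)
  list(model_dr = m_dr, model_rer = m_rer, bounds = bounds,
       w_dr = omega / den_dr, w_rer = (1 - omega) / den_rer,
       off = omega * (-bounds$abs_dr_min) / den_dr +
         (1 - omega) * (-bounds$rer_min) / den_rer)
}

predict_scalarized <- function(sur, newdata) {
  p1 <- predict(sur$model_dr, newdata, se.fit = TRUE)
  p2 <- predict(sur$model_rer, newdata, se.fit = TRUE)
  list(fit = sur$w_dr * abs(p1$fit) + sur$w_rer * p2$fit + sur$off,
       mse = sur$w_dr^2 * p1$mse + sur$w_rer^2 * p2$mse)
}

maximize_ei_scalarized <- function(sur, space, y_min, seed, n_starts) {
  m <- space_dim(space)
  ei_at <- function(uu) {
    p <- predict_scalarized(sur, scale_from_unit(uu, space$lower, space$upper))
    s2ref <- max(sur$w_dr^2 * sur$model_dr$sigma2 +
                   sur$w_rer^2 * sur$model_rer$sigma2, 0)
    ei <- numeric(length(p$fit))
    live <- p$mse > 1e-12 * s2ref
    if (any(live)) {
      s <- sqrt(p$mse[live])
      u <- (y_min - p$fit[live]) / s
      ei[live] <- s * (u * stats::pnorm(u) + stats::dnorm(u))
    }
    pmax(ei, 0)
  }
  x_best <- sur$model_dr$x[which.min(sur$model_dr$y), , drop = FALSE]
  starts <- with_seed(seed, rbind(
    scale_to_unit(x_best, space$lower, space$upper),
    matrix(stats::runif((n_starts - 1L) * m), ncol = m)))
  pars <- matrix(NA_real_, nrow(starts), m); eis <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], 0), 1),
                   function(u) -ei_at(rbind(u)), method = "L-BFGS-B",
                   lower = rep(0, m), upper = rep(1, m),
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit)) {
      pars[i, ] <- starts[i, ]; eis[i] <- ei_at(starts[i, , drop = FALSE])
    } else {
      pars[i, ] <- fit$par; eis[i] <- -fit$value
    }
  }
  ord <- order(eis, decreasing = TRUE)
  cand <- scale_from_unit(pars[ord, , drop = FALSE], space$lower, space$upper)
  colnames(cand) <- space$names
  list(par = stats::setNames(cand[1L, ], space$names), ei = eis[ord[1L]],
       degenerate = eis[ord[1L]] <= 1e-300, candidates = cand,
       ei_all = eis[ord])
}

# ---------------------------------------------------------------------------

#' Best evaluated design of a run
#'
#' The archive record with the minimal scalarized objective under the
#' current (final) normalization bounds; ties go to the earliest evaluation.
#'
#' @param state An [ego()] result.
#' @return A one-row data frame from the archive.
#' @export
incumbent <- function(state) {
  stopifnot(inherits(state, "ego"))
  if (nrow(state$archive) == 0L) stop("empty archive", call. = FALSE)
  state$archive[which.min(state$archive$objective), , drop = FALSE]
}

#' @export
print.ego <- function(x, ...) {
  cat(sprintf("Adaptive Kriging optimization: %d evaluations (%d infill), %s\n",
              nrow(x$archive), x$n_infill,
              if (x$converged) "converged" else "budget reached"))
  inc <- incumbent(x)
  cat("Incumbent:\n")
  print(inc, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ego <- function(object, ...) {
  inc <- incumbent(object)
  out <- list(n_total = nrow(object$archive), n_infill = object$n_infill,
              n_failures = length(object$failures),
              converged = object$converged,
              criteria_satisfied = object$criteria_satisfied,
              incumbent = inc, bounds = object$bounds,
              omega = object$config$omega,
              last_residuals = if (!is.null(object$trace))
                utils::tail(object$trace, 1L) else NULL)
  class(out) <- "summary.ego"
  out
}

#' @export
print.summary.ego <- function(x, ...) {
  cat(sprintf("EGO run: %d evaluations (%d infill, %d failed), omega = %g\n",
              x$n_total, x$n_infill, x$n_failures, x$omega))
  cat(sprintf("Converged: %s\n", x$converged))
  if (!is.null(x$last_residuals)) {
    cat("Last convergence residuals:\n")
    print(x$last_residuals[, c("ei_rel", "delta_f", "pred_gap")],
          row.names = FALSE)
  }
  cat("Incumbent:\n")
  print(x$incumbent, row.names = FALSE)
  invisible(x)
}

#' Convergence trace plot of an optimization run
#'
#' Plots the running best objective over infill iterations and, on a second
#' panel, the relative expected improvement (log scale).
#'
#' @param x An [ego()] result with at least one infill iteration.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.ego <- function(x, ...) {
  if (is.null(x$trace)) {
    stop("no infill iterations to plot", call. = FALSE)
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  inf <- x$archive[x$archive$iteration > 0L, ]
  best <- cummin(c(min(x$archive$objective[x$archive$iteration == 0L]),
                   inf$objective))
  plot(seq_along(best) - 1L, best, type = "s", xlab = "infill iteration",
       ylab = "best objective", ...)
  plot(x$trace$iteration, pmax(x$trace$ei_rel, 1e-16), type = "b", log = "y",
       xlab = "infill iteration", ylab = "relative EI", ...)
  invisible(x)
}

#' Optimize the stent design with the bundled simulator
#'
#' Convenience wrapper around [ego()] with the stent design box, the bundled
#' reduced-order evaluator and the reference design included in the initial
#' archive alongside the MRG samples.
#'
#' @param config A [stent_sim_config()].
#' @param n_initial Initial MRG sample size (default 30).
#' @param omega Dogboning weight (default 0.5).
#' @param tolerances An [ego_tolerances()].
#' @param seed Integer seed.
#' @param include_original Include [original_stent_design()] as a seed record
#'   of the initial archive (default `TRUE`).
#' @param ... Passed on to [ego()].
#' @return An [ego()] result.
#' @export
optimize_stent <- function(config = stent_sim_config(), n_initial = 30L,
                           omega = 0.5, tolerances = ego_tolerances(),
                           seed = NULL, include_original = TRUE, ...) {
  include <- if (include_original) rbind(original_stent_design()) else NULL
  ego(stent_evaluator(config), stent_design_space(), n_initial = n_initial,
      omega = omega, tolerances = tolerances, seed = seed, include = include,
      ...)
}
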