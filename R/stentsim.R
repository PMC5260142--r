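#' Configuration of the reduced-order stent-expansion simulator
#'
#' The bundled simulator is an invented analytic stand-in for a full
#' finite-element balloon-stent expansion: a smooth, deterministic
#' (at `noise_sd = 0`) map from design and inflation pressure to radial
#' displacements and point-of-interest radii.  Its coefficients are chosen so
#' that, over the stent design box, dogboning ratios and recoil fractions
#' fall in realistic ranges (|DR| up to about 0.36, RER about 0.013-0.023,
#' calibrated pressures about 1-2.5 MPa) and the canonical design trade-off
#' holds: wider bridge struts (`W5`) reduce recoil but raise radial force and
#' hence dogboning, while slimmer main struts and thickness reduce dogboning
#' at the cost of more recoil.  It makes no claim of finite-element fidelity.
#'
#' @param target_diameter Nominal post-recoil proximal diameter (mm) every
#'   design is dilated to; default 4.54.
#' @param pressure_bracket Pressure search bracket `(P_lo, P_hi)` in MPa for
#'   [find_pressure()]; default `c(0.5, 3)`.
#' @param noise_sd Standard deviation of optional Gaussian noise added to the
#'   radial displacements (mm); default 0 (deterministic).
#' @param coefficients Named list overriding individual model coefficients;
#'   see Details.
#'
#' @details Writing `mw` for the mean main-strut width and centring at the
#' original design (widths 0.28, `W5` 0.249, `T` 0.12 mm), the model is:
#' * stiffness `S = s0 (mw/0.28)^pw (T/0.12)^pt (1 + crf (W5 - 0.249))`;
#' * proximal loaded radius `r_p = r0 + P / S` (strictly increasing in `P`);
#' * recoil fraction
#'   `rho = rho0 exp(-k5 (W5 - 0.249)) (mw/0.28)^-qw (T/0.12)^-qt`;
#' * dogboning
#'   `DR = d0 (G - gref) + cl (L - lc)^2` with
#'   `G = (mw/0.28)^2 (T/0.12) (1 + c5 (W5 - 0.249))`, giving an interior
#'   minimum in the balloon length `L` and growth with stiffness;
#' * distal loaded radius `r_d = r0 + (1 + DR)(r_p - r0)`; all radii shrink
#'   by the factor `(1 - rho)` on unloading.
#'
#' @return A list of class `stent_sim_config`.
#' @export
stent_sim_config <- function(target_diameter = 4.54,
                             pressure_bracket = c(0.5, 3),
                             noise_sd = 0,
                             coefficients = list()) {
  coef <- list(
    r0 = 1.0,        # crimped outer radius, mm
    s0 = 1.4227,     # stiffness scale, MPa per mm of expansion
    pw = 1.0, pt = 0.5, crf = 0.3,          # stiffness exponents / W5 slope
    rho0 = 0.0178, k5 = 3.2, qw = 0.25, qt = 0.15,   # recoil model
    d0 = 0.301, gref = 0.8, c5 = 1.2, cl = 0.05, lc = 5.6,  # dogboning model
    poi_load = c(0.99, 1.01, 1.00, 1.00),   # POI spread at loading
    poi_recoil = c(0.97, 1.03, 1.01, 0.99)  # per-POI recoil modulation (mean 1)
  )
  if (length(coefficients)) {
    unknown <- setdiff(names(coefficients), names(coef))
    if (length(unknown)) {
      stop(sprintf("unknown simulator coefficient(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    coef[names(coefficients)] <- coefficients
  }
  if (target_diameter <= 0) stop("'target_diameter' must be positive", call. = FALSE)
  if (length(pressure_bracket) != 2L || pressure_bracket[1L] >= pressure_bracket[2L] ||
      pressure_bracket[1L] <= 0) {
    stop("'pressure_bracket' must be increasing positive (P_lo, P_hi)", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(target_diameter = target_diameter,
                 pressure_bracket = pressure_bracket,
                 noise_sd = noise_sd, coef = coef),
            class = "stent_sim_config")
}

# Design-dependent internals of the analytic model.
sim_internals <- function(design, coef) {
  d <- as.numeric(design)
  if (length(d) != 7L) stop("a stent design has 7 variables", call. = FALSE)
  mw <- mean(d[1:4]); w5 <- d[5L]; tt <- d[6L]; ll <- d[7L]
  S <- coef$s0 * (mw / 0.28)^coef$pw * (tt / 0.12)^coef$pt *
    (1 + coef$crf * (w5 - 0.249))
  rho <- coef$rho0 * exp(-coef$k5 * (w5 - 0.249)) *
    (mw / 0.28)^(-coef$qw) * (tt / 0.12)^(-coef$qt)
  G <- (mw / 0.28)^2 * (tt / 0.12) * (1 + coef$c5 * (w5 - 0.249))
  delta <- coef$d0 * (G - coef$gref) + coef$cl * (ll - coef$lc)^2
  list(S = S, rho = rho, delta = delta)
}

#' Simulate a balloon-stent expansion
#'
#' Evaluates the analytic expansion model of [stent_sim_config()] at a given
#' design and inflation pressure, returning the displacements and POI radii
#' at full expansion (loading) and after unloading.
#'
#' @param design A stent design vector (see [stent_design()]); out-of-box
#'   probe designs are accepted.
#' @param pressure Inflation pressure in MPa; must be positive.
#' @param config A [stent_sim_config()].
#' @return An [expansion_result()] including post-recoil displacements.
#' @export
simulate_expansion <- function(design, pressure, config = stent_sim_config()) {
  stopifnot(inherits(config, "stent_sim_config"))
  if (!is.numeric(pressure) || length(pressure) != 1L || !is.finite(pressure) ||
      pressure <= 0) {
    stop("'pressure' must be a single positive value (MPa)", call. = FALSE)
  }
  cf <- config$coef
  int <- sim_internals(design, cf)
  d_prox <- pressure / int$S
  d_dist <- (1 + int$delta) * d_prox
  if (config$noise_sd > 0) {
    d_prox <- d_prox + stats::rnorm(1L, 0, config$noise_sd)
    d_dist <- d_dist + stats::rnorm(1L, 0, config$noise_sd)
    if (d_prox <= 0) d_prox <- 1e-6
  }
  r_p <- cf$r0 + d_prox
  r_d <- cf$r0 + d_dist
  r_load <- r_p * cf$poi_load
  r_unload <- r_load * (1 - int$rho * cf$poi_recoil)
  expansion_result(
    d_radial_distal = d_dist,
    d_radial_proximal = d_prox,
    r_poi_loading = r_load,
    r_poi_unloading = r_unload,
    pressure = pressure,
    d_radial_distal_post = r_d * (1 - int$rho) - cf$r0,
    d_radial_proximal_post = r_p * (1 - int$rho) - cf$r0
  )
}

#' Calibrate the inflation pressure of a design by binary search
#'
#' Bisects the inflation pressure so that the post-recoil proximal diameter
#' of the design equals the configured nominal target (4.54 mm by default)
#' to within `1e-4` mm, mimicking the per-design load calibration of the
#' expansion analyses.  Calibration uses the noiseless model.
#'
#' @param design A stent design vector.
#' @param config A [stent_sim_config()]; its `pressure_bracket` must bracket
#'   the target (diameter below target at `P_lo`, above at `P_hi`).
#' @param tol Diameter tolerance in mm (default `1e-4`).
#' @param max_iter Bisection iteration cap (default 60).
#' @return Calibrated pressure in MPa.
#' @export
find_pressure <- function(design, config = stent_sim_config(), tol = 1e-4,
                          max_iter = 60L) {
  stopifnot(inherits(config, "stent_sim_config"))
  cf <- config$coef
  int <- sim_internals(design, cf)
  diam <- function(p) 2 * (cf$r0 + p / int$S) * (1 - int$rho)
  lo <- config$pressure_bracket[1L]
  hi <- config$pressure_bracket[2L]
  d_lo <- diam(lo); d_hi <- diam(hi)
  target <- config$target_diameter
  if (d_lo > target || d_hi < target) {
    stop(sprintf(paste0("pressure bracket does not bracket the target diameter: ",
                        "diameter %.4f mm at P = %.3f, %.4f mm at P = %.3f, ",
                        "target %.4f mm"),
                 d_lo, lo, d_hi, hi, target), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    d_mid <- diam(mid)
    if (abs(d_mid - target) <= tol / 10) break
    if (d_mid < target) lo <- mid else hi <- mid
  }
  mid
}

#' Evaluate a stent design end to end
#'
#' Composes [find_pressure()], [simulate_expansion()] and
#' [compute_metrics()]: the design is dilated to the nominal post-recoil
#' diameter and its dogboning ratios (at full expansion and post-recoil) and
#' radial elastic recoil are computed.
#'
#' @param design A stent design vector.
#' @param config A [stent_sim_config()].
#' @return A list of class `evaluation_record` with elements `design`,
#'   `pressure`, `expansion` (an [expansion_result()]) and `metrics`
#'   (a `metric_pair`).
#' @export
evaluate_design <- function(design, config = stent_sim_config()) {
  p <- find_pressure(design, config)
  expn <- simulate_expansion(design, p, config)
  structure(list(design = design, pressure = p, expansion = expn,
                 metrics = compute_metrics(expn)),
            class = "evaluation_record")
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat("Stent design evaluation\n")
  cat("  design: ", paste(sprintf("%s=%.4g", names(x$design), x$design),
                          collapse = " "), "\n")
  cat(sprintf("  calibrated pressure: %.4f MPa\n", x$pressure))
  cat(sprintf("  DR@32ms %.4f | DR@42ms %.4f | RER %.4f\n",
              x$metrics$dr, x$metrics$dr_post, x$metrics$rer))
  invisible(x)
}

#' Black-box evaluator backed by the bundled simulator
#'
#' Returns a function `design -> expansion_result` with the contract the
#' optimizer expects: every in-box design is dilated to the nominal diameter
#' by pressure calibration and its raw expansion outputs returned.
#'
#' @param config A [stent_sim_config()].
#' @return A function of one design vector.
#' @seealso [ego()] for running the optimization with this evaluator.
#' @export
stent_evaluator <- function(config = stent_sim_config()) {
  force(config)
  function(design) {
    simulate_expansion(design, find_pressure(design, config), config)
  }
}
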