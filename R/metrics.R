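#' Dogboning ratio
#'
#' Non-uniform balloon-stent expansion makes the stent ends flare relative to
#' the middle ("dogboning").  The dogboning ratio compares distal and proximal
#' radial displacements at full expansion:
#' \deqn{DR = (d_{distal} - d_{proximal}) / d_{proximal}}
#' `DR > 0` means the distal end over-expanded, `DR < 0` the proximal end.
#' Uniform expansion gives `DR = 0`; the optimization minimizes `|DR|`.
#'
#' @param d_distal Distal radial displacement (mm).
#' @param d_proximal Proximal radial displacement (mm); must be nonzero.
#' @return Dimensionless dogboning ratio.
#' @examples
#' dogboning_ratio(1.1, 1.0)   #  0.1 (distal over-expanded)
#' dogboning_ratio(0.9, 1.0)   # -0.1 (proximal over-expanded)
#' @export
dogboning_ratio <- function(d_distal, d_proximal) {
  if (!all(is.finite(d_distal)) || !all(is.finite(d_proximal))) {
    stop("displacements must be finite", call. = FALSE)
  }
  if (any(d_proximal == 0)) {
    stop("'d_proximal' is zero: dogboning ratio undefined", call. = FALSE)
  }
  (d_distal - d_proximal) / d_proximal
}

#' Radial elastic recoil
#'
#' Fractional loss of radius after balloon deflation, averaged over the four
#' points of interest (POIs) on the bridge struts:
#' \deqn{RER = \frac{1}{4}\sum_{i=1}^{4}
#'   \frac{R^{loading}_i - R^{unloading}_i}{R^{loading}_i}}
#'
#' @param r_loading Radii at the 4 POIs at full expansion (mm); all positive.
#' @param r_unloading Radii at the same POIs after unloading (mm).
#' @return Dimensionless mean recoil fraction.  A negative value (unloading
#'   radius above loading radius) is admissible but flagged with a warning.
#' @examples
#' radial_elastic_recoil(c(2, 2, 2, 2), c(1.9, 1.9, 1.9, 1.9))  # 0.05
#' @export
radial_elastic_recoil <- function(r_loading, r_unloading) {
  if (length(r_loading) != 4L || length(r_unloading) != 4L) {
    stop("recoil is measured at exactly 4 points of interest", call. = FALSE)
  }
  if (any(!is.finite(r_loading)) || any(!is.finite(r_unloading))) {
    stop("POI radii must be finite", call. = FALSE)
  }
  if (any(r_loading <= 0)) {
    stop("loading radii must be positive", call. = FALSE)
  }
  if (any(r_unloading > r_loading)) {
    warning("unloading radius exceeds loading radius at some POI (negative recoil)",
            call. = FALSE)
  }
  mean((r_loading - r_unloading) / r_loading)
}

#' Expansion-performance metrics of one simulated expansion
#'
#' Computes the dogboning ratio at full expansion (and, when post-recoil
#' displacements are present, after unloading) plus the radial elastic
#' recoil from an [expansion_result()].
#'
#' @param expansion An [expansion_result()].
#' @return A list of class `metric_pair` with elements `dr`, `dr_post`
#'   (`NA` when post-recoil displacements were not supplied) and `rer`.
#' @export
compute_metrics <- function(expansion) {
  stopifnot(inherits(expansion, "expansion_result"))
  dr <- dogboning_ratio(expansion$d_radial_distal, expansion$d_radial_proximal)
  dr_post <- NA_real_
  if (!is.null(expansion$d_radial_distal_post) &&
      !is.null(expansion$d_radial_proximal_post)) {
    dr_post <- dogboning_ratio(expansion$d_radial_distal_post,
                               expansion$d_radial_proximal_post)
  }
  rer <- radial_elastic_recoil(expansion$r_poi_loading, expansion$r_poi_unloading)
  structure(list(dr = dr, dr_post = dr_post, rer = rer), class = "metric_pair")
}

#' @export
print.metric_pair <- function(x, ...) {
  cat(sprintf("DR (full expansion): %.4f\n", x$dr))
  if (!is.na(x$dr_post)) cat(sprintf("DR (post-recoil):    %.4f\n", x$dr_post))
  cat(sprintf("RER:                 %.4f\n", x$rer))
  invisible(x)
}

#' Normalization bounds over an evaluated sample archive
#'
#' The scalarized objective normalizes `|DR|` and `RER` to `[0, 1]` by their
#' extrema over the samples evaluated so far.  These bounds are recomputed
#' each time the archive grows.
#'
#' @param dr Dogboning ratios (signed) of the archive.
#' @param rer Radial elastic recoils of the archive.
#' @return A list of class `normalization_bounds` with `abs_dr_min`,
#'   `abs_dr_max`, `rer_min`, `rer_max`.
#' @export
metric_bounds <- function(dr, rer) {
  if (length(dr) == 0L || length(rer) == 0L) {
    stop("cannot compute normalization bounds from an empty archive", call. = FALSE)
  }
  if (length(dr) != length(rer)) {
    stop("'dr' and 'rer' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(dr)) || any(!is.finite(rer))) {
    stop("archive metrics must be finite", call. = FALSE)
  }
  structure(
    list(abs_dr_min = min(abs(dr)), abs_dr_max = max(abs(dr)),
         rer_min = min(rer), rer_max = max(rer)),
    class = "normalization_bounds"
  )
}

#' Weighted-sum scalarized objective
#'
#' Collapses the two expansion metrics into one objective:
#' \deqn{f = \omega\frac{|DR| - |DR|_{min}}{|DR|_{max} - |DR|_{min}}
#'   + (1-\omega)\frac{RER - RER_{min}}{RER_{max} - RER_{min}}}
#' with extrema taken over the evaluated sample archive (see
#' [metric_bounds()]).  Values are not clipped: a design outside the
#' archive's metric range may legitimately scalarize outside `[0, 1]`.
#' When a denominator is degenerate (all archive values equal) that term is
#' defined as 0 and a warning is issued, which keeps the objective finite on
#' tiny archives.
#'
#' @param dr Dogboning ratio(s), signed; `|dr|` enters the objective.
#' @param rer Radial elastic recoil(s).
#' @param bounds A [metric_bounds()] object.
#' @param omega Weight on the dogboning term, in `(0, 1)`; default 0.5.
#' @return Scalarized objective value(s).
#' @export
scalarize <- function(dr, rer, bounds, omega = 0.5) {
  stopifnot(inherits(bounds, "normalization_bounds"))
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0 || omega >= 1) {
    stop("'omega' must be a single weight in (0, 1)", call. = FALSE)
  }
  den_dr <- bounds$abs_dr_max - bounds$abs_dr_min
  den_rer <- bounds$rer_max - bounds$rer_min
  if (den_dr > 0) {
    term_dr <- (abs(dr) - bounds$abs_dr_min) / den_dr
  } else {
    warning("degenerate |DR| bounds (max = min); dogboning term set to 0",
            call. = FALSE)
    term_dr <- rep(0, length(dr))
  }
  if (den_rer > 0) {
    term_rer <- (rer - bounds$rer_min) / den_rer
  } else {
    warning("degenerate RER bounds (max = min); recoil term set to 0",
            call. = FALSE)
    term_rer <- rep(0, length(rer))
  }
  omega * term_dr + (1 - omega) * term_rer
}

#' Percent reduction of a performance metric
#'
#' Reporting convention for before/after comparisons:
#' `100 * (|original| - |optimized|) / |original|`.
#'
#' @param original Metric value of the reference design; must be nonzero.
#' @param optimized Metric value of the improved design.
#' @return Reduction in percent (negative if the metric grew).
#' @examples
#' percent_reduction(0.0622, 0.0036)  # 94.21 (to 2 decimals)
#' @export
percent_reduction <- function(original, optimized) {
  if (any(original == 0)) {
    stop("'original' is zero: percent reduction undefined", call. = FALSE)
  }
  100 * (abs(original) - abs(optimized)) / abs(original)
}
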