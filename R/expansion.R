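#' Raw outputs of one balloon-stent expansion
#'
#' Container for the quantities a stent-expansion evaluation must report:
#' proximal and distal radial displacements at full expansion, the radii at
#' the four bridge-strut points of interest (POIs) at full expansion and
#' after unloading, the applied inflation pressure, and (optionally) the
#' post-recoil displacements used for the post-recoil dogboning ratio.
#'
#' @param d_radial_distal,d_radial_proximal Radial displacements (mm) at the
#'   distal and proximal ends at full expansion.
#' @param r_poi_loading,r_poi_unloading Length-4 positive radii (mm) at the
#'   POIs at full expansion and after unloading.
#' @param pressure Applied inflation pressure (MPa).
#' @param d_radial_distal_post,d_radial_proximal_post Optional post-recoil
#'   radial displacements (mm); when supplied, [compute_metrics()] also
#'   reports the post-recoil dogboning ratio.
#' @return An object of class `expansion_result`.
#' @export
expansion_result <- function(d_radial_distal, d_radial_proximal,
                             r_poi_loading, r_poi_unloading, pressure,
                             d_radial_distal_post = NULL,
                             d_radial_proximal_post = NULL) {
  if (length(r_poi_loading) != 4L || length(r_poi_unloading) != 4L) {
    stop("exactly 4 POI radii are required for loading and unloading",
         call. = FALSE)
  }
  vals <- c(d_radial_distal, d_radial_proximal, r_poi_loading, r_poi_unloading,
            pressure, d_radial_distal_post, d_radial_proximal_post)
  if (any(!is.finite(vals))) stop("expansion outputs must be finite", call. = FALSE)
  if (any(r_poi_loading <= 0) || any(r_poi_unloading <= 0)) {
    stop("POI radii must be positive", call. = FALSE)
  }
  if (any(r_poi_unloading > r_poi_loading)) {
    warning("unloading radius exceeds loading radius at some POI (negative recoil)",
            call. = FALSE)
  }
  structure(
    list(d_radial_distal = d_radial_distal,
         d_radial_proximal = d_radial_proximal,
         r_poi_loading = as.numeric(r_poi_loading),
         r_poi_unloading = as.numeric(r_poi_unloading),
         pressure = pressure,
         d_radial_distal_post = d_radial_distal_post,
         d_radial_proximal_post = d_radial_proximal_post),
    class = "expansion_result"
  )
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("Expansion at P = %.4f MPa\n", x$pressure))
  cat(sprintf("  radial displacement: proximal %.4f mm, distal %.4f mm\n",
              x$d_radial_proximal, x$d_radial_distal))
  cat(sprintf("  POI radii (loading):   %s mm\n",
              paste(sprintf("%.4f", x$r_poi_loading), collapse = " ")))
  cat(sprintf("  POI radii (unloading): %s mm\n",
              paste(sprintf("%.4f", x$r_poi_unloading), collapse = " ")))
  invisible(x)
}
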