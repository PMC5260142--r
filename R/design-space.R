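#' Define a box-constrained design space
#'
#' A design space is a hyper-rectangle `[lower_j, upper_j]`, one interval per
#' design variable, together with a per-dimension level count used by the
#' rectangular-grid sampling functions ([rg_sample()], [mrg_sample()]).
#'
#' @param lower,upper Numeric vectors of equal length `m`; `lower < upper`
#'   elementwise.
#' @param names Optional character vector of variable labels (defaults to
#'   `x1 ... xm`, or the names of `lower` if set).
#' @param levels Integer level counts `q_j >= 2`, recycled to length `m`.
#'   Controls the grid resolution of rectangular-grid sampling.
#' @return An object of class `design_space` with elements `lower`, `upper`,
#'   `levels` and `names`.
#' @seealso [stent_design_space()] for the stent design box used throughout.
#' @examples
#' design_space(c(0, 0), c(1, 2), names = c("a", "b"), levels = 3)
#' @export
design_space <- function(lower, upper, names = NULL, levels = 2L) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  m <- length(lower)
  if (length(upper) != m) {
    stop("'lower' and 'upper' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("design-space bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    bad <- which(lower >= upper)[1L]
    stop(sprintf("lower bound must be strictly below upper bound (dimension %d)", bad),
         call. = FALSE)
  }
  levels <- as.integer(rep_len(levels, m))
  if (any(is.na(levels)) || any(levels < 2L)) {
    stop("'levels' must be integers >= 2", call. = FALSE)
  }
  if (is.null(names)) {
    names <- if (!is.null(base::names(lower))) base::names(lower) else paste0("x", seq_len(m))
  }
  if (length(names) != m) stop("'names' must have one label per dimension", call. = FALSE)
  structure(
    list(lower = unname(lower), upper = unname(upper),
         levels = levels, names = as.character(names)),
    class = "design_space"
  )
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("Design space: %d variables\n", length(x$lower)))
  print(data.frame(variable = x$names, lower = x$lower, upper = x$upper,
                   levels = x$levels), row.names = FALSE)
  invisible(x)
}

#' Dimension of a design space
#' @param space A [design_space()].
#' @return Integer number of design variables.
#' @export
space_dim <- function(space) {
  stopifnot(inherits(space, "design_space"))
  length(space$lower)
}

#' The stent design box
#'
#' The seven-variable constraint box for the balloon-stent system: strut
#' widths `W1..W4` in `[0.22, 0.34]` mm, bridge-strut width `W5` in
#' `[0.2, 0.3]` mm, stent thickness `T` in `[0.1, 0.14]` mm and balloon
#' length `L` in `[4.5, 6.5]` mm.
#'
#' @param levels Grid level counts for DOE sampling, recycled to 7 dimensions
#'   (default 2, a 128-cell grid).
#' @return A [design_space()] with variables `W1, W2, W3, W4, W5, T, L`.
#' @export
stent_design_space <- function(levels = 2L) {
  design_space(
    lower = c(0.22, 0.22, 0.22, 0.22, 0.20, 0.10, 4.5),
    upper = c(0.34, 0.34, 0.34, 0.34, 0.30, 0.14, 6.5),
    names = c("W1", "W2", "W3", "W4", "W5", "T", "L"),
    levels = levels
  )
}

#' Construct a stent design vector
#'
#' @param w1,w2,w3,w4 Strut widths (mm).
#' @param w5 Bridge-strut width (mm).
#' @param t Stent thickness (mm).
#' @param l Balloon length (mm).
#' @param validate If `TRUE` (default) the design must lie inside the stent
#'   design box; if `FALSE` out-of-box probe designs are permitted.
#' @return A named numeric vector `c(W1..W5, T, L)`.
#' @export
stent_design <- function(w1, w2, w3, w4, w5, t, l, validate = TRUE) {
  x <- c(W1 = w1, W2 = w2, W3 = w3, W4 = w4, W5 = w5, T = t, L = l)
  if (any(!is.finite(x))) stop("design variables must be finite", call. = FALSE)
  if (validate) {
    space <- stent_design_space()
    out <- x < space$lower - 1e-12 | x > space$upper + 1e-12
    if (any(out)) {
      stop(sprintf("design outside the constraint box: %s",
                   paste(space$names[out], collapse = ", ")), call. = FALSE)
    }
  }
  x
}

#' The original (pre-optimization) stent design
#'
#' Uniform 0.28 mm strut widths, 0.249 mm bridge struts, 0.12 mm thickness
#' and a 5.8 mm balloon — the reference geometry that optimized designs are
#' compared against.
#'
#' @return A named design vector (see [stent_design()]).
#' @export
original_stent_design <- function() {
  stent_design(0.28, 0.28, 0.28, 0.28, 0.249, 0.12, 5.8)
}

# Check containment of points (rows) in a design space box.
in_box <- function(x, space, tol = 1e-12) {
  x <- rbind(x)
  apply(x, 1L, function(p) {
    all(p >= space$lower - tol) && all(p <= space$upper + tol)
  })
}
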