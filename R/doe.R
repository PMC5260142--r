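#' Narrowed upper bounds for rectangular-grid sampling
#'
#' The modified rectangular grid first shrinks each variable's range so that
#' a half grid step is reserved at the top of every dimension:
#' \deqn{\hat u_j = u_j - \frac{1}{2}\frac{u_j - l_j}{q_j - 1}}
#' The stochastic displacement later applied by [mrg_sample()] is at most
#' that reserved half step, so perturbed points never leave the original box.
#'
#' @param space A [design_space()] (all `levels >= 2`).
#' @return Numeric vector of narrowed upper bounds.
#' @export
narrowed_upper <- function(space) {
  stopifnot(inherits(space, "design_space"))
  space$upper - 0.5 * (space$upper - space$lower) / (space$levels - 1)
}

#' Rectangular-grid (full factorial) sample in the narrowed space
#'
#' Generates all `prod(levels)` points
#' `x_j = l_j + k_j (u_hat_j - l_j)/(q_j - 1)`, `k_j = 0, ..., q_j - 1`,
#' on the narrowed box of [narrowed_upper()].
#'
#' @param space A [design_space()].
#' @param max_points Guard on the grid size; exceeding it is an error
#'   (full factorial grids grow as `prod(q_j)`).
#' @return A numeric matrix with one row per grid point and named columns,
#'   with the integer grid coordinates in attribute `"grid_index"`.
#' @export
rg_sample <- function(space, max_points = 1e5) {
  stopifnot(inherits(space, "design_space"))
  n_grid <- prod(space$levels)
  if (n_grid > max_points) {
    stop(sprintf(paste0("full factorial grid has %g points, above the cap of %g; ",
                        "reduce 'levels' or draw a subset with mrg_sample()"),
                 n_grid, max_points), call. = FALSE)
  }
  idx <- as.matrix(expand.grid(lapply(space$levels, function(q) 0:(q - 1L))))
  dimnames(idx) <- list(NULL, space$names)
  u_hat <- narrowed_upper(space)
  step <- (u_hat - space$lower) / (space$levels - 1)
  pts <- sweep(sweep(idx, 2L, step, "*"), 2L, space$lower, "+")
  attr(pts, "grid_index") <- idx
  pts
}

#' Modified rectangular grid (MRG) sample
#'
#' Draws `n` space-filling points: a rectangular-grid point per selected grid
#' cell (see [rg_sample()]) plus an independent per-dimension displacement
#' \deqn{\frac{\alpha_{ij}}{2}\frac{u_j - l_j}{q_j - 1}, \qquad
#'   \alpha_{ij} \in [0, 1],}
#' which keeps points off the box boundary faces shared by the grid while
#' guaranteeing the minimum pairwise spacing of [min_distance_bound()].
#' The `alpha` displacements are drawn from a Normal(0.5, 1/6) truncated to
#' `[0, 1]` (honouring both the stated support and the stated family).
#'
#' When `n` is below the full grid size, distinct grid cells are chosen by a
#' seeded greedy maximin-distance rule: starting from a random cell, each
#' subsequent cell maximizes its minimum distance to the cells already
#' selected (earliest index wins ties).
#'
#' @param space A [design_space()].
#' @param n Number of points, `1 <= n <= prod(levels)`.
#' @param seed Integer seed making cell selection and displacement
#'   reproducible; `NULL` uses the current RNG stream.
#' @param alpha Test hook: a scalar or `n x m` matrix of displacement
#'   fractions in `[0, 1]` overriding the random draw (`alpha = 0`
#'   reproduces the plain rectangular grid on the selected cells).
#' @param max_points Grid-size guard passed to the underlying grid.
#' @return An object of class `mrg_sample`: list with `points` (`n x m`
#'   matrix), `grid_index` (integer cell coordinates), `seed` and `space`.
#' @export
mrg_sample <- function(space, n, seed = NULL, alpha = NULL, max_points = 1e5) {
  stopifnot(inherits(space, "design_space"))
  n <- as.integer(n)
  n_grid <- prod(space$levels)
  if (n < 1L || n > n_grid) {
    stop(sprintf("'n' must be between 1 and the grid size (%d)", n_grid),
         call. = FALSE)
  }
  grid <- rg_sample(space, max_points = max_points)
  idx <- attr(grid, "grid_index")
  m <- space_dim(space)

  with_seed(seed, {
    if (n < n_grid) {
      sel <- greedy_maximin(grid, n)
    } else {
      sel <- seq_len(n_grid)
    }
    pts <- grid[sel, , drop = FALSE]
    cell <- idx[sel, , drop = FALSE]
    if (is.null(alpha)) {
      a <- matrix(rtnorm01(n * m), nrow = n, ncol = m)
    } else {
      a <- matrix(alpha, nrow = n, ncol = m)
      if (any(a < 0) || any(a > 1)) {
        stop("'alpha' fractions must lie in [0, 1]", call. = FALSE)
      }
    }
    disp <- sweep(a / 2, 2L, (space$upper - space$lower) / (space$levels - 1), "*")
    pts <- pts + disp
    dimnames(pts) <- list(NULL, space$names)
    structure(list(points = pts, grid_index = cell, seed = seed, space = space),
              class = "mrg_sample")
  })
}

# Truncated Normal(0.5, 1/6) on [0, 1] via inverse-CDF (fully seed-driven).
rtnorm01 <- function(n, mean = 0.5, sd = 1 / 6) {
  p_lo <- stats::pnorm(0, mean, sd)
  p_hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

# Greedy maximin subset of the rows of a candidate matrix; seeded start,
# earliest-index tie-break thereafter.
greedy_maximin <- function(cand, n) {
  n_cand <- nrow(cand)
  sel <- integer(n)
  sel[1L] <- sample.int(n_cand, 1L)
  # running minimum distance from each candidate to the selected set
  d_min <- sqrt(rowSums(sweep(cand, 2L, cand[sel[1L], ], "-")^2))
  d_min[sel[1L]] <- -Inf
  for (k in seq_len(n - 1L)) {
    nxt <- which.max(d_min)          # which.max takes the earliest tie
    sel[k + 1L] <- nxt
    d_new <- sqrt(rowSums(sweep(cand, 2L, cand[nxt, ], "-")^2))
    d_min <- pmin(d_min, d_new)
    d_min[nxt] <- -Inf
  }
  sel
}

#' @export
print.mrg_sample <- function(x, ...) {
  cat(sprintf("MRG sample: %d points in %d dimensions (seed %s)\n",
              nrow(x$points), ncol(x$points),
              if (is.null(x$seed)) "none" else x$seed))
  print(utils::head(round(x$points, 4)))
  if (nrow(x$points) > 6L) cat(sprintf("... %d more rows\n", nrow(x$points) - 6L))
  invisible(x)
}

#' Guaranteed minimum pairwise distance of an MRG sample
#'
#' Any two MRG points from distinct grid cells are at least
#' \deqn{\min_j \frac{u_j - l_j}{2(q_j - 1)}\left(1 - \frac{1}{q_j - 1}\right)}
#' apart: adjacent cells in dimension `j` are one narrowed grid step apart
#' and each point moves by at most half an original step, which leaves
#' exactly this margin.  For `q_j = 2` the bound degenerates to 0.
#'
#' @param space A [design_space()].
#' @return The distance bound (same units as the design variables).
#' @export
min_distance_bound <- function(space) {
  stopifnot(inherits(space, "design_space"))
  q <- space$levels
  min((space$upper - space$lower) / (2 * (q - 1)) * (1 - 1 / (q - 1)))
}

#' Verify the MRG spacing guarantee on a sample
#'
#' Brute-force check that the minimum pairwise Euclidean distance of a sample
#' meets the [min_distance_bound()] of its design space (inclusive).
#' Distances are computed in the native units of the variables.
#'
#' @param sample An [mrg_sample()] object or a point matrix (>= 2 rows).
#' @param space The [design_space()]; defaults to the sample's own space.
#' @param scaled If `TRUE`, also report the minimum distance after scaling
#'   the points to the unit cube (diagnostic only; the pass flag always uses
#'   native units).
#' @return A list with `min_distance`, `bound`, `pass` and (optionally)
#'   `min_distance_scaled`.
#' @export
validate_spacing <- function(sample, space = NULL, scaled = FALSE) {
  if (inherits(sample, "mrg_sample")) {
    if (is.null(space)) space <- sample$space
    pts <- sample$points
  } else {
    pts <- rbind(sample)
  }
  if (is.null(space)) stop("'space' is required for a bare point matrix", call. = FALSE)
  if (nrow(pts) < 2L) {
    stop("spacing validation needs at least 2 points", call. = FALSE)
  }
  d_min <- min(stats::dist(pts))
  bound <- min_distance_bound(space)
  out <- list(min_distance = d_min, bound = bound, pass = d_min >= bound)
  if (scaled) {
    out$min_distance_scaled <-
      min(stats::dist(scale_to_unit(pts, space$lower, space$upper)))
  }
  out
}
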