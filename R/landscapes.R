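# Persistence landscapes: one-parameter landscapes from barcodes and
# multiparameter landscapes from bifiltrations by diagonal slicing.

#' One-parameter persistence landscape
#'
#' For a barcode with bars \[b, d) the k-th landscape level at t is the k-th
#' largest of the tent values max(0, min(t - b, d - t)); infinite bars
#' contribute t - b.
#'
#' @param bc a barcode from [compute_barcode()], or a two-column matrix of
#'   (birth, death) pairs.
#' @param grid sorted numeric vector of evaluation points.
#' @param k_max number of landscape levels.
#' @param dim homology dimension selected from the barcode (default 1).
#' @return numeric matrix `k_max x length(grid)`; row k is lambda(k, .).
#' @export
landscape_1d <- function(bc, grid, k_max = 4L, dim = 1L) {
  if (is.unsorted(grid)) stop("grid must be sorted")
  if (inherits(bc, "barcode") || is.data.frame(bc)) {
    sel <- bc$dimension == dim
    bars <- cbind(bc$birth[sel], bc$death[sel])
  } else {
    bars <- matrix(as.numeric(bc), ncol = 2)
  }
  out <- matrix(0, nrow = k_max, ncol = length(grid))
  if (nrow(bars) == 0L) return(out)
  for (ti in seq_along(grid)) {
    t <- grid[ti]
    v <- pmin(t - bars[, 1], ifelse(is.finite(bars[, 2]), bars[, 2] - t, Inf))
    v <- v[v > 0]
    if (length(v) == 0L) next
    v <- sort(v, decreasing = TRUE)
    kk <- min(k_max, length(v))
    out[seq_len(kk), ti] <- v[seq_len(kk)]
  }
  out
}

#' Multiparameter persistence landscape of a bifiltration
#'
#' The k-th MPH landscape at parameter x is the largest h >= 0 such that the
#' rank of the map H1(K_(x - h(1,1))) -> H1(K_(x + h(1,1))) is at least k:
#' it measures the prominence of the k-th most prominent loop at x, in units
#' of the normalized filtration axes. The production path slices the
#' bifiltration along the diagonal lines through the grid anti-diagonals
#' (y = x + offset in normalized coordinates): on each line the restriction
#' is an ordinary filtration whose barcode yields the landscape exactly at
#' every grid point on that line, with no interpolation. The equality with
#' the sup-h rank search is checked against [rank_invariant()] in the test
#' suite.
#'
#' @param bif a `bifiltered_complex` with normalized grades, e.g. from
#'   [build_function_rips_bifiltration()].
#' @param grid_size number of grid points per axis (the square grid covers
#'   the normalized unit square). Grid resolution is the accuracy knob for
#'   all landscape-derived quadratures and is recorded in the result.
#' @param k_max number of landscape levels (default 4).
#' @return an `mph_landscape`: list with `values` (array `k_max x g x g`,
#'   dimensions level, x, y), normalized grids, and axis metadata.
#' @export
compute_mph_landscape <- function(bif, grid_size = 60L, k_max = 4L) {
  g <- as.integer(grid_size)
  if (g < 2L) stop("grid_size must be at least 2")
  vals <- cpp_mph_landscape(bif$n_vertices, bif$vertex_grades[, 1],
                            bif$edges, bif$edge_grades[, 1],
                            bif$edge_grades[, 2], bif$triangle_edges,
                            bif$triangle_grades[, 1],
                            bif$triangle_grades[, 2], g, as.integer(k_max))
  structure(list(values = vals, k_max = as.integer(k_max),
                 x_grid = seq(0, 1, length.out = g),
                 y_grid = seq(0, 1, length.out = g),
                 axes = bif$axes),
            class = "mph_landscape")
}

#' @export
print.mph_landscape <- function(x, ...) {
  cat(sprintf("mph_landscape: %d levels on a %d x %d grid (%s x %s)\n",
              x$k_max, length(x$x_grid), length(x$y_grid),
              x$axes$x_name, x$axes$y_name))
  cat(sprintf("  max lambda(1) = %.4g (normalized units)\n",
              max(x$values[1, , ])))
  invisible(x)
}

# physical coordinates of the landscape grid axes
landscape_axis_physical <- function(L, axis = c("x", "y")) {
  axis <- match.arg(axis)
  rng <- if (axis == "x") L$axes$x_range else L$axes$y_range
  grid <- if (axis == "x") L$x_grid else L$y_grid
  rng[1] + grid * (rng[2] - rng[1])
}

#' Radius-codensity MPH landscapes for a collection of point clouds
#'
#' Convenience batch path for comparative analyses (PCA, norm
#' distributions, classification): computes the k-nearest-neighbor
#' codensity of every cloud and one MPH landscape per cloud, with a single
#' shared normalization of both axes so the landscapes live on a common
#' parameter rectangle and are comparable as feature vectors.
#'
#' By default the codensity axis spans `[0, f_scale * Q]` where `Q` is the
#' largest per-cloud `f_quantile` codensity quantile across the
#' collection. This confines the parameter rectangle to the bulk of the
#' codensity distribution: sparse outlier points, whose codensity lies in
#' the upper tail, then enter the filtration beyond the rectangle, so
#' loops that exist only in their presence do not contribute -- which is
#' the purpose of filtering by codensity in the first place.
#'
#' @param clouds list of [point_cloud()] objects.
#' @param k codensity neighbor index (default 5).
#' @param max_radius common Rips truncation scale, at least the death scale
#'   of the largest loop of interest.
#' @param grid_size,k_max landscape grid resolution and number of levels.
#' @param f_range explicit common codensity range, overriding the robust
#'   default.
#' @param f_quantile,f_scale parameters of the robust range (defaults 0.8
#'   and 1.15).
#' @return list of `mph_landscape` objects on a common grid; the chosen
#'   codensity range is attached as attribute `"f_range"`.
#' @export
codensity_landscapes <- function(clouds, k = 5L, max_radius,
                                 grid_size = 15L, k_max = 4L,
                                 f_range = NULL, f_quantile = 0.8,
                                 f_scale = 1.15) {
  fs <- lapply(clouds, knn_codensity, k = k)
  if (is.null(f_range)) {
    f_range <- c(0, f_scale *
                   max(vapply(fs, quantile, numeric(1), probs = f_quantile)))
  }
  out <- mapply(function(cl, f) {
    bif <- build_function_rips_bifiltration(cl, f, max_radius = max_radius,
                                            f_range = f_range)
    compute_mph_landscape(bif, grid_size = grid_size, k_max = k_max)
  }, clouds, fs, SIMPLIFY = FALSE)
  attr(out, "f_range") <- f_range
  out
}

#' Lp norm of an MPH landscape
#'
#' Discretized Lp norm by trapezoidal quadrature on the landscape grid over
#' the selected levels. With `units = "normalized"` (default) both axes are
#' the unit square; with `units = "physical"` the integration measure uses
#' the physical axis ranges (landscape values themselves remain in
#' normalized filtration units, since a diagonal mixes the two physical
#' scales).
#'
#' @param L an `mph_landscape`.
#' @param p norm exponent (default 2, the "2-norm of the MPH landscape").
#' @param levels landscape levels to stack (default 1).
#' @param units `"normalized"` or `"physical"`.
#' @return nonnegative scalar.
#' @export
landscape_norm <- function(L, p = 2, levels = 1L,
                           units = c("normalized", "physical")) {
  units <- match.arg(units)
  if (!all(levels %in% seq_len(L$k_max))) stop("levels must lie in 1..k_max")
  xg <- L$x_grid; yg <- L$y_grid
  if (units == "physical") {
    xg <- landscape_axis_physical(L, "x")
    yg <- landscape_axis_physical(L, "y")
  }
  w <- outer(trapezoid_weights(xg), trapezoid_weights(yg))
  total <- 0
  for (k in levels) total <- total + sum((L$values[k, , ]^p) * w)
  total^(1 / p)
}

#' Pointwise mean of MPH landscapes
#'
#' Arithmetic mean per level and grid point. Note the mean is taken level by
#' level: the level-ordering property lambda(k) >= lambda(k+1) survives
#' averaging, but the mean of level k is not in general the k-th landscape
#' of any single module.
#'
#' @param Ls a list of `mph_landscape` objects on identical grids.
#' @return an `mph_landscape`.
#' @export
mean_landscape <- function(Ls) {
  if (length(Ls) == 0L) stop("need at least one landscape")
  ref <- Ls[[1]]
  for (L in Ls) {
    if (!identical(dim(L$values), dim(ref$values)) ||
        !isTRUE(all.equal(L$x_grid, ref$x_grid)) ||
        !isTRUE(all.equal(L$y_grid, ref$y_grid)))
      stop("landscapes must share an identical grid")
  }
  vals <- Reduce(`+`, lapply(Ls, `[[`, "values")) / length(Ls)
  out <- ref
  out$values <- vals
  out
}

#' Radius profile of an MPH landscape
#'
#' Integrates the first landscape level along the second-parameter
#' (codensity) axis at each radius grid value, summarizing the prevalence
#' of loops as a function of the radius parameter. The codensity axis is
#' integrated in physical units; the radius column of the result is in
#' physical units too.
#'
#' @param L an `mph_landscape`.
#' @param level landscape level to profile (default 1).
#' @return data frame with columns `radius` (physical units) and `value`.
#' @export
radius_profile <- function(L, level = 1L) {
  wx <- trapezoid_weights(landscape_axis_physical(L, "x"))
  vals <- L$values[level, , , drop = TRUE]
  data.frame(radius = landscape_axis_physical(L, "y"),
             value = as.numeric(crossprod(wx, vals)))
}

#' Integral of the landscape over large radius parameters
#'
#' Integrates lambda(1) over the grid points with physical radius at least
#' `radius_min` (inclusive), over both axes in physical units. The
#' statistic indicates the presence of large voids formed by the cells; the
#' study threshold is 240 micrometers for 1.5 mm regions of interest.
#'
#' @param L an `mph_landscape`.
#' @param radius_min lower radius cutoff in physical units (default 240).
#' @param level landscape level (default 1).
#' @return nonnegative scalar; 0 with a warning if `radius_min` exceeds the
#'   grid range.
#' @export
restricted_radius_integral <- function(L, radius_min = 240, level = 1L) {
  yphys <- landscape_axis_physical(L, "y")
  keep <- yphys >= radius_min
  if (!any(keep)) {
    warning("radius_min is beyond the landscape grid; returning 0")
    return(0)
  }
  wx <- trapezoid_weights(landscape_axis_physical(L, "x"))
  wy <- trapezoid_weights(yphys[keep])
  vals <- L$values[level, , keep, drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = sum(keep))
  sum(outer(wx, wy) * vals)
}
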