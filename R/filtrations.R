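# One- and two-parameter filtered complexes from point clouds:
# Vietoris-Rips in the radius parameter, crossed with codensity or an
# ordinal hypoxia value in the second parameter.

#' k-nearest-neighbor codensity
#'
#' The empirical codensity of a point is its Euclidean distance to its k-th
#' nearest neighbor (self excluded); larger values mean sparser
#' neighborhoods. Filtering a complex by codensity admits points from dense
#' regions first, which suppresses outliers. The default k = 5 is the
#' fifth-nearest-neighbor codensity used throughout the pipeline.
#'
#' Values are permutation-invariant and invariant under translations and
#' rotations of the cloud. Ties among equal distances are immaterial: the
#' k-th order statistic is well defined regardless of index order.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k neighbor index (default 5).
#' @return numeric vector of per-point codensity values (length units).
#' @export
knn_codensity <- function(cloud, k = 5L) {
  n <- n_points(cloud)
  if (n <= k) stop("codensity needs more than k = ", k, " points")
  d <- as.matrix(dist(cloud$points))
  diag(d) <- Inf
  unname(apply(d, 1L, function(row) sort(row, partial = k)[k]))
}

#' Ordinal hypoxia value of tissue categories
#'
#' Maps the five tissue categories to 0..4 in order of increasing hypoxia:
#' Stroma 0, PanCK 1, CAIX 2, Pimo 3, Necrosis 4. Used as the second
#' (sublevel) filtration parameter, admitting the best-oxygenated cells
#' first, mirroring the codensity filtration.
#'
#' @param tissue character vector of categories from [TISSUE_LEVELS].
#' @return integer vector of values in 0..4.
#' @export
tissue_ordinal <- function(tissue) {
  idx <- match(as.character(tissue), TISSUE_LEVELS)
  if (anyNA(idx))
    stop("unknown tissue categories: ",
         paste(unique(tissue[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' One-parameter Vietoris-Rips filtration
#'
#' Builds the Rips filtration of a cloud up to dimension 2 with the diameter
#' convention: an edge enters at the distance between its endpoints (the
#' diameter of the two balls drawn at the points when they touch), a
#' triangle at the value of its longest edge, vertices at 0. Simplices with
#' entry value above `max_radius` are omitted.
#'
#' @param cloud a [point_cloud()].
#' @param max_radius truncation scale (> 0), same units as the coordinates.
#' @param max_dim 1 (graph only) or 2 (default; needed for loop deaths).
#' @return a `filtered_complex` object.
#' @export
build_rips_filtration <- function(cloud, max_radius, max_dim = 2L) {
  if (max_radius <= 0) stop("max_radius must be > 0")
  if (!max_dim %in% c(1L, 2L)) stop("max_dim must be 1 or 2")
  rc <- cpp_rips_complex(cloud$points[, 1], cloud$points[, 2], max_radius)
  if (max_dim < 2L) {
    rc$triangles <- matrix(integer(0), ncol = 3)
    rc$triangle_edges <- matrix(integer(0), ncol = 3)
    rc$triangle_values <- numeric(0)
  }
  filtered_complex(n_vertices = n_points(cloud),
                   vertex_values = rep(0, n_points(cloud)),
                   edges = rc$edges, edge_values = rc$edge_values,
                   triangles = rc$triangles,
                   triangle_edges = rc$triangle_edges,
                   triangle_values = rc$triangle_values)
}

#' Filtered simplicial complex (dimension <= 2)
#'
#' Container for a one-parameter filtration: simplices with one real entry
#' value each, monotone from faces to cofaces.
#'
#' @param n_vertices number of vertices (entry values in `vertex_values`).
#' @param vertex_values,edge_values,triangle_values entry values.
#' @param edges integer matrix (m x 2) of 1-based vertex indices, i < j.
#' @param triangles integer matrix (t x 3) of 1-based vertex indices.
#' @param triangle_edges integer matrix (t x 3): for each triangle the
#'   indices of its three edges in `edges`; computed when missing.
#' @return a `filtered_complex` object.
#' @export
filtered_complex <- function(n_vertices, vertex_values, edges, edge_values,
                             triangles = matrix(integer(0), ncol = 3),
                             triangle_edges = NULL,
                             triangle_values = numeric(0)) {
  edges <- matrix(as.integer(edges), ncol = 2)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (is.null(triangle_edges)) triangle_edges <- match_triangle_edges(edges, triangles)
  triangle_edges <- matrix(as.integer(triangle_edges), ncol = 3)
  fc <- structure(list(n_vertices = as.integer(n_vertices),
                       vertex_values = as.numeric(vertex_values),
                       edges = edges, edge_values = as.numeric(edge_values),
                       triangles = triangles,
                       triangle_edges = triangle_edges,
                       triangle_values = as.numeric(triangle_values)),
                  class = "filtered_complex")
  validate_monotone(fc)
  fc
}

# locate each triangle's edges in the edge list (1-based)
match_triangle_edges <- function(edges, triangles) {
  if (nrow(triangles) == 0L) return(matrix(integer(0), ncol = 3))
  key <- function(i, j) pmin(i, j) * (2^26) + pmax(i, j)
  ekey <- key(edges[, 1], edges[, 2])
  te <- cbind(match(key(triangles[, 1], triangles[, 2]), ekey),
              match(key(triangles[, 1], triangles[, 3]), ekey),
              match(key(triangles[, 2], triangles[, 3]), ekey))
  if (anyNA(te)) stop("triangle with a missing face edge")
  te
}

validate_monotone <- function(fc) {
  if (nrow(fc$edges) > 0L) {
    vmax <- pmax(fc$vertex_values[fc$edges[, 1]], fc$vertex_values[fc$edges[, 2]])
    if (any(fc$edge_values < vmax - 1e-12))
      stop("filtration not monotone: edge enters before a vertex face")
  }
  if (nrow(fc$triangles) > 0L) {
    emax <- pmax(fc$edge_values[fc$triangle_edges[, 1]],
                 pmax(fc$edge_values[fc$triangle_edges[, 2]],
                      fc$edge_values[fc$triangle_edges[, 3]]))
    if (any(fc$triangle_values < emax - 1e-12))
      stop("filtration not monotone: triangle enters before an edge face")
  }
  invisible(fc)
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat(sprintf("filtered_complex: %d vertices, %d edges, %d triangles\n",
              x$n_vertices, nrow(x$edges), nrow(x$triangles)))
  invisible(x)
}

#' Function-Rips bifiltration of a point cloud
#'
#' Builds the one-critical bifiltration whose complex at parameter value
#' (x, y) is the Rips complex at scale y on the points with second-parameter
#' value f at most x: a simplex enters at the grade (max of f over its
#' vertices, Rips entry value). Both axes are affinely normalized onto
#' \[0, 1\] -- the second parameter by `f_range`, the radius by
#' `[0, max_radius]` -- so that the two parameters vary over similar scales;
#' the scale factors are recorded in the axis metadata and all landscape
#' values are reported in these normalized units unless converted back.
#'
#' @param cloud a [point_cloud()].
#' @param f per-point second-parameter value (e.g. [knn_codensity()] or
#'   [tissue_ordinal()]); finite.
#' @param max_radius Rips truncation scale (> 0).
#' @param f_range length-2 range used to normalize `f`; defaults to
#'   `range(f)`. Values outside the range are allowed and map outside
#'   \[0, 1\].
#' @param x_name,y_name axis names recorded in the metadata.
#' @return a `bifiltered_complex` with normalized entry grades.
#' @export
build_function_rips_bifiltration <- function(cloud, f, max_radius,
                                             f_range = NULL,
                                             x_name = "codensity",
                                             y_name = "radius") {
  if (max_radius <= 0) stop("max_radius must be > 0")
  f <- as.numeric(f)
  if (length(f) != n_points(cloud)) stop("f must have one value per point")
  if (!all(is.finite(f))) stop("f must be finite")
  if (is.null(f_range)) f_range <- range(f)
  fr <- diff(f_range)
  fx <- if (fr > 0) (f - f_range[1]) / fr else rep(0, length(f))
  rc <- cpp_rips_complex(cloud$points[, 1], cloud$points[, 2], max_radius)
  e <- rc$edges
  ea <- pmax(fx[e[, 1]], fx[e[, 2]])
  eb <- rc$edge_values / max_radius
  tr <- rc$triangles
  if (nrow(tr) > 0L) {
    ta <- pmax(fx[tr[, 1]], pmax(fx[tr[, 2]], fx[tr[, 3]]))
    tb <- rc$triangle_values / max_radius
  } else {
    ta <- tb <- numeric(0)
  }
  bifiltered_complex(n_vertices = n_points(cloud),
                     vertex_grades = cbind(fx, rep(0, length(fx))),
                     edges = e, edge_grades = cbind(ea, eb),
                     triangles = tr, triangle_edges = rc$triangle_edges,
                     triangle_grades = cbind(ta, tb),
                     axes = list(x_name = x_name, y_name = y_name,
                                 x_range = as.numeric(f_range),
                                 y_range = c(0, max_radius),
                                 units = attr(cloud, "units") %||% "um"))
}

#' One-critical bifiltered simplicial complex (dimension <= 2)
#'
#' Each simplex carries a single minimal entry grade (x, y) in normalized
#' coordinates; grades are coordinatewise monotone from faces to cofaces.
#' Axis metadata records the affine map back to physical units.
#'
#' @param n_vertices,edges,triangles,triangle_edges as in
#'   [filtered_complex()].
#' @param vertex_grades,edge_grades,triangle_grades two-column matrices of
#'   entry grades.
#' @param axes list with `x_name`, `y_name`, `x_range`, `y_range`, `units`.
#' @return a `bifiltered_complex` object.
#' @export
bifiltered_complex <- function(n_vertices, vertex_grades, edges, edge_grades,
                               triangles = matrix(integer(0), ncol = 3),
                               triangle_edges = NULL,
                               triangle_grades = matrix(numeric(0), ncol = 2),
                               axes = list(x_name = "x", y_name = "y",
                                           x_range = c(0, 1),
                                           y_range = c(0, 1), units = "")) {
  edges <- matrix(as.integer(edges), ncol = 2)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (is.null(triangle_edges)) triangle_edges <- match_triangle_edges(edges, triangles)
  vertex_grades <- matrix(as.numeric(vertex_grades), ncol = 2)
  edge_grades <- matrix(as.numeric(edge_grades), ncol = 2)
  triangle_grades <- matrix(as.numeric(triangle_grades), ncol = 2)
  bif <- structure(list(n_vertices = as.integer(n_vertices),
                        vertex_grades = vertex_grades,
                        edges = edges, edge_grades = edge_grades,
                        triangles = triangles,
                        triangle_edges = matrix(as.integer(triangle_edges),
                                                ncol = 3),
                        triangle_grades = triangle_grades,
                        axes = axes),
                   class = "bifiltered_complex")
  validate_bigrade_monotone(bif)
  bif
}

validate_bigrade_monotone <- function(bif) {
  for (col in 1:2) {
    if (nrow(bif$edges) > 0L) {
      vmax <- pmax(bif$vertex_grades[bif$edges[, 1], col],
                   bif$vertex_grades[bif$edges[, 2], col])
      if (any(bif$edge_grades[, col] < vmax - 1e-12))
        stop("bifiltration not monotone on axis ", col)
    }
    if (nrow(bif$triangles) > 0L) {
      emax <- pmax(bif$edge_grades[bif$triangle_edges[, 1], col],
                   pmax(bif$edge_grades[bif$triangle_edges[, 2], col],
                        bif$edge_grades[bif$triangle_edges[, 3], col]))
      if (any(bif$triangle_grades[, col] < emax - 1e-12))
        stop("bifiltration not monotone on axis ", col)
    }
  }
  invisible(bif)
}

#' @export
print.bifiltered_complex <- function(x, ...) {
  cat(sprintf(
    "bifiltered_complex: %d vertices, %d edges, %d triangles\n  axes: %s in [%.4g, %.4g], %s in [%.4g, %.4g] (normalized to [0,1])\n",
    x$n_vertices, nrow(x$edges), nrow(x$triangles),
    x$axes$x_name, x$axes$x_range[1], x$axes$x_range[2],
    x$axes$y_name, x$axes$y_range[1], x$axes$y_range[2]))
  invisible(x)
}

#' Restrict a bifiltration to a diagonal line
#'
#' On the line \{(u, u + offset)\} in normalized coordinates, a simplex with
#' grade (a, b) first satisfies (a, b) <= (u, u + offset) at
#' u = max(a, b - offset); the restriction is therefore an ordinary
#' filtration in u whose barcode encodes the rank invariant between any two
#' comparable points of the line.
#'
#' @param bif a `bifiltered_complex` (normalized grades).
#' @param offset intercept of the diagonal line y = x + offset.
#' @return a [filtered_complex()] filtered by the line parameter u.
#' @export
restrict_to_diagonal <- function(bif, offset) {
  entry <- function(g) pmax(g[, 1], g[, 2] - offset)
  filtered_complex(n_vertices = bif$n_vertices,
                   vertex_values = entry(bif$vertex_grades),
                   edges = bif$edges, edge_values = entry(bif$edge_grades),
                   triangles = bif$triangles,
                   triangle_edges = bif$triangle_edges,
                   triangle_values = entry(bif$triangle_grades))
}
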