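#' Tissue categories in order of increasing hypoxia
#'
#' Ordinal oxygenation classes assigned per cell from IHC markers: stromal
#' tissue, better-oxygenated tumor (pancytokeratin), moderate hypoxia
#' (carbonic anhydrase IX, ~20 mm Hg), severe hypoxia (pimonidazole,
#' ~10 mm Hg), and necrosis (virtually anoxic).
#' @export
TISSUE_LEVELS <- c("Stroma", "PanCK", "CAIX", "Pimo", "Necrosis")

#' Labeled 2D point cloud of cell centers
#'
#' The universal input of the pipeline: cell-center coordinates with a
#' categorical cell-type label per point, an optional ordinal tissue
#' (hypoxia) category, and an axis-aligned observation window.
#'
#' @param points numeric matrix (or data frame) with two columns, the x and
#'   y coordinates. Units are micrometers for histology data and cell
#'   diameters for agent-based model output.
#' @param labels optional character vector of per-point cell types.
#' @param tissue optional character vector of per-point tissue categories,
#'   drawn from [TISSUE_LEVELS].
#' @param window numeric vector `c(xmin, xmax, ymin, ymax)`. Defaults to the
#'   tight bounding box of the points.
#' @param units length unit tag, `"um"` or `"cell_diameter"`.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, labels = NULL, tissue = NULL, window = NULL,
                        units = "um") {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 2)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  n <- nrow(points)
  if (is.null(window)) {
    window <- if (n == 0L) c(0, 0, 0, 0) else
      c(range(points[, 1]), range(points[, 2]))
  }
  window <- as.numeric(window)
  if (length(window) != 4L || window[1] > window[2] || window[3] > window[4])
    stop("`window` must be c(xmin, xmax, ymin, ymax) with xmin <= xmax, ymin <= ymax")
  if (n > 0L) {
    inside <- points[, 1] >= window[1] & points[, 1] <= window[2] &
      points[, 2] >= window[3] & points[, 2] <= window[4]
    if (!all(inside)) stop("every point must lie inside the window")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("`labels` must have one entry per point")
  }
  if (!is.null(tissue)) {
    tissue <- as.character(tissue)
    if (length(tissue) != n) stop("`tissue` must have one entry per point")
    bad <- setdiff(unique(tissue), TISSUE_LEVELS)
    if (length(bad) > 0L)
      stop("unknown tissue categories: ", paste(bad, collapse = ", "))
  }
  structure(list(points = points, labels = labels, tissue = tissue,
                 window = window),
            units = units, class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points in window [%.4g, %.4g] x [%.4g, %.4g] (%s)\n",
              nrow(x$points), x$window[1], x$window[2], x$window[3],
              x$window[4], attr(x, "units") %||% "um"))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$tissue)) {
    tab <- table(factor(x$tissue, levels = TISSUE_LEVELS))
    cat("  tissue:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of points in a point cloud
#' @param cloud a [point_cloud()].
#' @export
n_points <- function(cloud) nrow(cloud$points)

# subset a cloud by index, carrying labels/tissue along
cloud_subset <- function(cloud, idx, window = cloud$window) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              tissue = if (!is.null(cloud$tissue)) cloud$tissue[idx],
              window = window, units = attr(cloud, "units") %||% "um")
}
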