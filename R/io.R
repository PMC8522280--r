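# Readers/writers for the point-cloud tabular format and region-of-interest
# sampling from annotated masks.
#
# Coordinate convention: origin at the lower-left of each region, y
# increasing upward, units micrometers (beware image conventions with y
# flipped).

#' Write a point cloud to CSV
#'
#' Comma-separated with header `x,y[,label][,tissue]`. Coordinates are
#' written with 17 significant digits so a write/read round trip preserves
#' them exactly.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @export
write_point_cloud <- function(cloud, path) {
  df <- data.frame(x = formatC(cloud$points[, 1], format = "g", digits = 17),
                   y = formatC(cloud$points[, 2], format = "g", digits = 17))
  if (!is.null(cloud$labels)) df$label <- cloud$labels
  if (!is.null(cloud$tissue)) df$tissue <- cloud$tissue
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a point cloud from CSV
#'
#' Expects a header `x,y[,label][,tissue]`. Malformed coordinate rows are
#' reported with their line number; tissue categories are validated
#' against [TISSUE_LEVELS].
#'
#' @param path input path.
#' @param window optional window; defaults to the tight bounding box.
#' @param units length unit tag (default micrometers).
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, window = NULL, units = "um") {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("point-cloud file must have a header with columns x,y: ", path)
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0L)
    stop(sprintf("malformed coordinate in %s at line %d", path, bad[1] + 1L))
  point_cloud(cbind(x, y),
              labels = if ("label" %in% names(df) && nrow(df) > 0) df$label,
              tissue = if ("tissue" %in% names(df) && nrow(df) > 0) df$tissue,
              window = window, units = units)
}

square_inside_polygon <- function(origin, side, mask) {
  # probe points pulled fractionally inward so squares that share an edge
  # with the mask boundary still count as inside
  s <- c(1e-9, 0.5, 1 - 1e-9)
  probe <- as.matrix(expand.grid(origin[1] + s * side, origin[2] + s * side))
  if (!all(mgcv::in.out(mask, probe))) return(FALSE)
  # a mask vertex strictly inside the square would mean the boundary dips in
  inside <- mask[, 1] > origin[1] & mask[, 1] < origin[1] + side &
    mask[, 2] > origin[2] & mask[, 2] < origin[2] + side
  !any(inside)
}

squares_overlap <- function(a, b, side) {
  abs(a[1] - b[1]) < side && abs(a[2] - b[2]) < side
}

#' Sample nonoverlapping square regions of interest from a masked cloud
#'
#' Places axis-aligned, pairwise disjoint squares of side `side` fully
#' inside a polygonal mask until saturation, and returns the clipped
#' sub-cloud of each region in region-local coordinates (origin at the
#' lower-left corner). The default placement is greedy random: candidate
#' origins are drawn uniformly and accepted if the square fits and does not
#' overlap an accepted region, stopping after `max_attempts` consecutive
#' rejections. `method = "grid"` instead walks a regular grid anchored at
#' the mask bounding box corner.
#'
#' @param cloud a [point_cloud()].
#' @param mask polygon as a two-column matrix of vertices (closed
#'   implicitly).
#' @param side square side length (default 1500, micrometers).
#' @param seed integer seed (random method).
#' @param method `"random"` (default) or `"grid"`.
#' @param max_attempts rejection cap for the random method.
#' @return list of `list(roi = list(origin, side, id), cloud = point_cloud)`;
#'   empty list if no square fits.
#' @export
sample_rois <- function(cloud, mask, side = 1500, seed = 1L,
                        method = c("random", "grid"), max_attempts = 10000L) {
  method <- match.arg(method)
  mask <- as.matrix(mask)
  if (ncol(mask) != 2L || nrow(mask) < 3L)
    stop("mask must be a polygon with at least 3 vertices")
  bb <- c(range(mask[, 1]), range(mask[, 2]))
  origins <- list()
  if (method == "grid") {
    xs <- seq(bb[1], bb[2] - side, by = side)
    ys <- seq(bb[3], bb[4] - side, by = side)
    if (bb[2] - bb[1] >= side && bb[4] - bb[3] >= side) {
      for (ox in xs) for (oy in ys) {
        if (square_inside_polygon(c(ox, oy), side, mask))
          origins[[length(origins) + 1L]] <- c(ox, oy)
      }
    }
  } else {
    with_seed(seed, {
      fails <- 0L
      while (fails < max_attempts &&
             bb[2] - bb[1] >= side && bb[4] - bb[3] >= side) {
        o <- c(runif(1, bb[1], bb[2] - side), runif(1, bb[3], bb[4] - side))
        ok <- square_inside_polygon(o, side, mask) &&
          !any(vapply(origins, squares_overlap, logical(1), b = o,
                      side = side))
        if (ok) {
          origins[[length(origins) + 1L]] <- o
          fails <- 0L
        } else {
          fails <- fails + 1L
        }
      }
    })
  }
  lapply(seq_along(origins), function(i) {
    o <- origins[[i]]
    sel <- cloud$points[, 1] >= o[1] & cloud$points[, 1] < o[1] + side &
      cloud$points[, 2] >= o[2] & cloud$points[, 2] < o[2] + side
    sub <- cloud_subset(cloud, which(sel), window = cloud$window)
    sub$points[, 1] <- sub$points[, 1] - o[1]
    sub$points[, 2] <- sub$points[, 2] - o[2]
    sub$window <- c(0, side, 0, side)
    list(roi = list(origin = o, side = side, id = i), cloud = sub)
  })
}

#' Save / load an MPH landscape bundle
#'
#' Serializes the landscape container (grids, values, axis metadata) to an
#' RDS bundle; [write_radius_profile()] exports the profile curve as CSV.
#'
#' @param L an `mph_landscape`.
#' @param path output path.
#' @export
write_landscape <- function(L, path) {
  saveRDS(unclass(L), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  structure(readRDS(path), class = "mph_landscape")
}

#' Export a radius profile as CSV
#' @param L an `mph_landscape`.
#' @param path output path; columns `radius`, `value`.
#' @export
write_radius_profile <- function(L, path) {
  write.csv(radius_profile(L), path, row.names = FALSE)
  invisible(path)
}
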