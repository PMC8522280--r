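# Synthetic point-cloud generators: ring mixtures, complete spatial
# randomness, misclassification noise, and tissue-category scenes.

#' Specification of one noisy ring
#'
#' A ring fixture consists of points sampled uniformly on a circle with
#' radial Gaussian jitter, plus outlier points sampled uniformly in the open
#' disk enclosed by the ring.
#'
#' @param center numeric length-2 center of the ring.
#' @param radius ring radius (> 0).
#' @param n_ring number of points sampled uniformly on the circle.
#' @param n_interior number of outlier points sampled uniformly in the
#'   enclosed open disk.
#' @param jitter_sd standard deviation of the radial Gaussian noise applied
#'   to ring points; defaults to 5% of the radius.
#' @return a `ring_spec` object.
#' @export
ring_spec <- function(center, radius, n_ring = 80L, n_interior = 20L,
                      jitter_sd = 0.05 * radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("ring radius must be a positive number")
  if (n_ring < 0L || n_interior < 0L) stop("point counts must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(center = as.numeric(center), radius = radius,
                 n_ring = as.integer(n_ring),
                 n_interior = as.integer(n_interior),
                 jitter_sd = jitter_sd),
            class = "ring_spec")
}

#' Sample a mixture of noisy rings
#'
#' Draws the union of ring samples and interior outliers for a sequence of
#' ring specifications. The same seed always reproduces the identical cloud.
#'
#' @param specs a list of [ring_spec()] objects (a single spec is accepted).
#' @param seed integer seed; required for reproducibility.
#' @param units length unit tag for the output cloud.
#' @return a [point_cloud()] whose window is the tight bounding box padded
#'   by the largest `jitter_sd` among the specs. Labels record the ring of
#'   origin (`ring<i>`) and interior outliers (`interior<i>`).
#' @export
sample_ring_mixture <- function(specs, seed, units = "cell_diameter") {
  if (inherits(specs, "ring_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("`specs` must be nonempty")
  for (s in specs) {
    if (!inherits(s, "ring_spec")) stop("all specs must be ring_spec objects")
  }
  with_seed(seed, {
    pts <- vector("list", length(specs))
    labs <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      theta <- runif(s$n_ring, 0, 2 * pi)
      r <- s$radius + if (s$jitter_sd > 0) rnorm(s$n_ring, 0, s$jitter_sd) else 0
      ring <- cbind(s$center[1] + r * cos(theta), s$center[2] + r * sin(theta))
      phi <- runif(s$n_interior, 0, 2 * pi)
      rho <- s$radius * sqrt(runif(s$n_interior))
      inner <- cbind(s$center[1] + rho * cos(phi), s$center[2] + rho * sin(phi))
      pts[[i]] <- rbind(ring, inner)
      labs[[i]] <- c(rep(paste0("ring", i), s$n_ring),
                     rep(paste0("interior", i), s$n_interior))
    }
    pts <- do.call(rbind, pts)
    labs <- unlist(labs)
    pad <- max(vapply(specs, function(s) s$jitter_sd, numeric(1)))
    window <- if (nrow(pts) == 0L) c(0, 0, 0, 0) else
      c(range(pts[, 1]) + c(-pad, pad), range(pts[, 2]) + c(-pad, pad))
    point_cloud(pts, labels = labs, window = window, units = units)
  })
}

# Default ring geometries for the two fixture families. The three medium
# rings sit at the vertices of an equilateral triangle wide enough that no
# inter-ring edge forms below the analysis truncation scale (3.6 length
# units): closer spacing would let the rings connect and bound a spurious
# fourth loop in the central gap, which the three-loop fixture must not
# contain.
rings_default_specs <- function(kind) {
  switch(kind,
    "3rings" = list(
      ring_spec(c(0, 0), 1.5), ring_spec(c(7.2, 0), 1.5),
      ring_spec(c(3.6, 6.235), 1.5)),
    "2rings" = list(
      ring_spec(c(0, 0), 2), ring_spec(c(5, 0), 0.7)),
    stop("unknown rings dataset kind: ", kind))
}

#' Generate replicate ring-fixture datasets
#'
#' The `"3rings"` family is three disjoint equal-radius rings (three medium
#' loops of the same scale); `"2rings"` is one large, sparsely sampled ring
#' and one small, densely sampled ring (both carry 80 ring points, so the
#' larger circumference is the sparser). Each replicate is drawn with an
#' independently derived seed so the sequence is reproducible as a whole.
#'
#' @param kind `"3rings"` or `"2rings"`.
#' @param n_replicates number of independent clouds to draw (>= 1).
#' @param seed integer seed for the whole dataset.
#' @param specs optional list of [ring_spec()] overriding the default
#'   geometry for this kind.
#' @return a list of [point_cloud()] objects.
#' @export
make_rings_dataset <- function(kind = c("3rings", "2rings"), n_replicates,
                               seed, specs = NULL) {
  kind <- match.arg(kind)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (is.null(specs)) specs <- rings_default_specs(kind)
  lapply(seq_len(n_replicates), function(i) {
    sample_ring_mixture(specs, seed = derive_seed(seed, i))
  })
}

#' Sample complete spatial randomness
#'
#' `n` points i.i.d. uniform on a rectangular window; the null model against
#' which the pair-correlation function is calibrated (g(r) = 1).
#'
#' @param n number of points (>= 0).
#' @param window `c(xmin, xmax, ymin, ymax)` with positive area.
#' @param seed integer seed.
#' @param units length unit tag.
#' @return a [point_cloud()].
#' @export
sample_csr <- function(n, window, seed, units = "um") {
  if (n < 0L) stop("n must be >= 0")
  window <- as.numeric(window)
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3])
    stop("window must have positive area")
  with_seed(seed, {
    pts <- cbind(runif(n, window[1], window[2]), runif(n, window[3], window[4]))
    point_cloud(pts, window = window, units = units)
  })
}

#' Inject misclassification noise into a point cloud
#'
#' Emulates falsely registered cells: each point of `other_cells` is
#' independently mislabeled as the true class with probability `p` and added
#' to `true_cells`. With the study default p = 0.01 and ~2,000 tumor cells
#' this yields ~20 false positives next to ~100 true macrophages.
#'
#' @param true_cells [point_cloud()] of the true class.
#' @param other_cells [point_cloud()] of cells at risk of mislabeling.
#' @param p mislabeling probability in \[0, 1\].
#' @param seed integer seed.
#' @param label label assigned to injected points; defaults to the first
#'   label of `true_cells` (or `"true"` if unlabeled).
#' @return a [point_cloud()] of the true cells plus injected points; the
#'   logical attribute `"injected"` flags the injected points for
#'   diagnostics.
#' @export
add_misclassification_noise <- function(true_cells, other_cells, p, seed,
                                        label = NULL) {
  if (p < 0 || p > 1) stop("p must be a probability in [0, 1]")
  if (is.null(label))
    label <- if (!is.null(true_cells$labels)) true_cells$labels[1] else "true"
  n_other <- n_points(other_cells)
  pick <- with_seed(seed, runif(n_other) < p)
  win <- c(min(true_cells$window[1], other_cells$window[1]),
           max(true_cells$window[2], other_cells$window[2]),
           min(true_cells$window[3], other_cells$window[3]),
           max(true_cells$window[4], other_cells$window[4]))
  if (n_points(true_cells) == 0L && !any(pick)) {
    out <- true_cells
  } else {
    pts <- rbind(true_cells$points, other_cells$points[pick, , drop = FALSE])
    labs <- if (!is.null(true_cells$labels) || sum(pick) > 0L) {
      c(true_cells$labels %||% rep(label, n_points(true_cells)),
        rep(label, sum(pick)))
    }
    out <- point_cloud(pts, labels = labs, window = win,
                       units = attr(true_cells, "units") %||% "um")
  }
  attr(out, "injected") <- c(rep(FALSE, n_points(true_cells)),
                             rep(TRUE, sum(pick)))
  out
}

#' Synthesize a tissue scene with ordinal hypoxia bands
#'
#' Builds a scene reminiscent of tumor tissue surrounding a necrotic core:
#' concentric circular bands Necrosis < Pimo < CAIX < PanCK, with Stroma
#' outside the outermost band. Cells of each type are placed uniformly in
#' the window outside their per-type exclusion radius, so a small exclusion
#' radius lets a cell type infiltrate deep into the hypoxic core.
#'
#' @param n_per_type number of cells per cell type.
#' @param band_radii named increasing radii of the band outer edges, in
#'   order `Necrosis`, `Pimo`, `CAIX`, `PanCK` (Stroma is everything
#'   beyond `PanCK`).
#' @param exclusion named numeric: per-type minimal distance from the scene
#'   center (infiltration depth control). Names define the cell types.
#' @param seed integer seed.
#' @param window_half half-side of the square window; defaults to 1.5 times
#'   the outermost band radius.
#' @param units length unit tag.
#' @return a [point_cloud()] with `labels` (cell type) and `tissue` filled.
#' @export
synth_tissue_scene <- function(n_per_type = 1500L,
                               band_radii = c(Necrosis = 150, Pimo = 300,
                                              CAIX = 450, PanCK = 700),
                               exclusion = c(CD8 = 350, FoxP3 = 350,
                                             CD68 = 120),
                               seed,
                               window_half = NULL, units = "um") {
  need <- c("Necrosis", "Pimo", "CAIX", "PanCK")
  if (!all(need %in% names(band_radii)))
    stop("band_radii must name Necrosis, Pimo, CAIX and PanCK")
  radii <- band_radii[need]
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("band radii must be strictly increasing (nested bands)")
  if (is.null(window_half)) window_half <- 1.5 * radii[["PanCK"]]
  if (any(exclusion < 0) || any(exclusion > window_half))
    stop("exclusion radii must lie in [0, window_half]")
  types <- names(exclusion)
  with_seed(seed, {
    pts <- vector("list", length(types))
    for (ti in seq_along(types)) {
      excl <- exclusion[[ti]]
      got <- matrix(numeric(0), ncol = 2)
      while (nrow(got) < n_per_type) {
        m <- 2L * (n_per_type - nrow(got)) + 16L
        cand <- cbind(runif(m, -window_half, window_half),
                      runif(m, -window_half, window_half))
        keep <- sqrt(rowSums(cand^2)) >= excl
        got <- rbind(got, cand[keep, , drop = FALSE])
      }
      pts[[ti]] <- got[seq_len(n_per_type), , drop = FALSE]
    }
    pts <- do.call(rbind, pts)
    labs <- rep(types, each = n_per_type)
    r <- sqrt(rowSums(pts^2))
    tissue <- cut(r, breaks = c(-Inf, radii, Inf),
                  labels = c(need, "Stroma"))
    point_cloud(pts, labels = labs, tissue = as.character(tissue),
                window = c(-window_half, window_half, -window_half,
                           window_half),
                units = units)
  })
}
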