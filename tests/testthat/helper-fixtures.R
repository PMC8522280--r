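# Shared fixtures and independent oracles for the test suite.

# four corners of the unit square: one H1 bar [1, sqrt(2))
unit_square_cloud <- function() {
  point_cloud(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

regular_polygon_cloud <- function(n, radius = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  point_cloud(cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th)))
}

random_bifiltration <- function(n, seed, max_radius = 1.2) {
  cl <- with_test_seed(seed, point_cloud(cbind(runif(n), runif(n))))
  f <- with_test_seed(seed + 1, runif(n))
  build_function_rips_bifiltration(cl, f, max_radius = max_radius)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force MPH landscape via the rank-invariant sup-h search, at a single
# grid point. Candidate h values are the points where a slice entry crosses
# u; between consecutive candidates the rank is constant, so evaluating at
# midpoints determines sup{h : rank >= k} exactly. Uses that the rank is
# nonincreasing in h (verified separately) for a binary search.
oracle_landscape_at <- function(bif, x, y, k) {
  off <- y - x
  entries <- c(pmax(bif$vertex_grades[, 1], -off),
               pmax(bif$edge_grades[, 1], bif$edge_grades[, 2] - off),
               pmax(bif$triangle_grades[, 1], bif$triangle_grades[, 2] - off))
  hs <- sort(unique(c(0, abs(x - entries))))
  if (length(hs) == 1L) return(0)
  rank_at_mid <- function(i) {
    h <- (hs[i - 1] + hs[i]) / 2
    rank_invariant(bif, c(x - h, y - h), c(x + h, y + h), dim = 1L)
  }
  lo <- 2L; hi <- length(hs); best <- 0
  if (rank_at_mid(2L) < k) return(0)
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (rank_at_mid(mid) >= k) {
      best <- hs[mid]
      lo <- mid + 1L
    } else {
      hi <- mid - 1L
    }
  }
  best
}

oracle_landscape_grid <- function(bif, g, k_max) {
  grid <- seq(0, 1, length.out = g)
  out <- array(0, dim = c(k_max, g, g))
  for (i in seq_len(g)) for (j in seq_len(g)) for (k in seq_len(k_max))
    out[k, i, j] <- oracle_landscape_at(bif, grid[i], grid[j], k)
  out
}

# distance from a point to the boundary of the convex hull of a cloud
dist_to_hull <- function(p, pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  seg_dist <- function(a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  min(vapply(seq_len(nh), function(i) {
    seg_dist(hull[i, ], hull[if (i == nh) 1L else i + 1L, ])
  }, numeric(1)))
}

# memoized short ABM runs shared between test blocks
.abm_cache <- new.env(parent = emptyenv())
cached_abm_run <- function(chi, seed, duration = 20) {
  key <- paste(chi, seed, duration, sep = "_")
  if (is.null(.abm_cache[[key]])) {
    p <- abm_params(duration = duration)
    .abm_cache[[key]] <- run_abm(chi, seed = seed, params = p)
  }
  .abm_cache[[key]]
}

sorted_bars <- function(bc, dim) {
  b <- bc[bc$dimension == dim, c("birth", "death")]
  b[order(b$birth, b$death), , drop = FALSE]
}
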