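test_that("knn codensity is the distance to the k-th nearest neighbor", {
  # 6 collinear points at x = 0..5: 5th neighbor of the end point is at 5
  line <- point_cloud(cbind(0:5, 0))
  expect_equal(knn_codensity(line, 5)[1], 5)
  expect_equal(knn_codensity(line, 5)[2], 4) # point at 1: 5th NN is at 5

  # a point with >= 5 coincident duplicates has codensity 0
  dup <- point_cloud(rbind(matrix(0.5, 6, 2), cbind(runif(5), runif(5))))
  expect_equal(knn_codensity(dup, 5)[1], 0)

  expect_error(knn_codensity(point_cloud(cbind(1:3, 1:3)), 5), "points")
})

test_that("codensity marks an outlier as sparsest (brute-force check)", {
  set.seed(8)
  pts <- rbind(cbind(rnorm(30, 0, 0.3), rnorm(30, 0, 0.3)), c(8, 8))
  cl <- point_cloud(pts)
  f <- knn_codensity(cl, 5)
  # brute force over the full distance matrix
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  brute <- unname(apply(d, 1, function(r) sort(r)[5]))
  expect_equal(f, brute)
  expect_equal(which.max(f), 31L)
})

test_that("codensity is invariant under rigid motions and relabeling", {
  set.seed(9)
  pts <- cbind(runif(40), runif(40))
  f0 <- knn_codensity(point_cloud(pts), 5)
  th <- 0.7
  rot <- pts %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  f1 <- knn_codensity(point_cloud(sweep(rot, 2, c(-3, 11), "+")), 5)
  expect_equal(f1, f0, tolerance = 1e-10)
  perm <- sample(40)
  f2 <- knn_codensity(point_cloud(pts[perm, ]), 5)
  expect_equal(f2, f0[perm])
})

test_that("tissue ordinal maps the five categories in hypoxia order", {
  expect_equal(tissue_ordinal(c("Stroma", "PanCK", "CAIX", "Pimo",
                                "Necrosis")), 0:4)
  expect_equal(tissue_ordinal(rep("Stroma", 4)), rep(0L, 4))
  expect_error(tissue_ordinal("Tumour"), "unknown tissue")
})

test_that("Rips filtration uses the diameter convention and truncates", {
  cl <- unit_square_cloud()
  fc <- build_rips_filtration(cl, max_radius = 2)
  expect_equal(fc$n_vertices, 4L)
  expect_equal(nrow(fc$edges), 6L)
  expect_equal(sort(fc$edge_values), sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))))
  expect_equal(nrow(fc$triangles), 4L)
  # triangle entry = longest edge
  expect_equal(unique(fc$triangle_values), sqrt(2))
  # truncation below the diagonal removes it
  fc2 <- build_rips_filtration(cl, max_radius = 1.2)
  expect_equal(nrow(fc2$edges), 4L)
  expect_equal(nrow(fc2$triangles), 0L)
  expect_error(build_rips_filtration(cl, max_radius = 0))
})

test_that("bifiltration grades are one-critical and monotone", {
  for (seed in 1:5) {
    bif <- random_bifiltration(20, seed)
    # every edge dominates its endpoints, every triangle its edges, in
    # both coordinates
    for (col in 1:2) {
      vmax <- pmax(bif$vertex_grades[bif$edges[, 1], col],
                   bif$vertex_grades[bif$edges[, 2], col])
      expect_true(all(bif$edge_grades[, col] >= vmax))
      if (nrow(bif$triangles) > 0) {
        emax <- pmax(bif$edge_grades[bif$triangle_edges[, 1], col],
                     pmax(bif$edge_grades[bif$triangle_edges[, 2], col],
                          bif$edge_grades[bif$triangle_edges[, 3], col]))
        expect_true(all(bif$triangle_grades[, col] >= emax))
      }
    }
  }
})

test_that("axis normalization maps data ranges onto the unit square", {
  cl <- with_test_seed(3, point_cloud(cbind(runif(15), runif(15))))
  f <- with_test_seed(4, runif(15, 2, 6))
  bif <- build_function_rips_bifiltration(cl, f, max_radius = 0.9)
  expect_equal(range(bif$vertex_grades[, 1]), c(0, 1))
  expect_true(all(bif$edge_grades[, 2] <= 1))
  expect_equal(bif$axes$x_range, range(f))
  expect_equal(bif$axes$y_range, c(0, 0.9))
  # constant second parameter collapses to the zero column
  bif0 <- build_function_rips_bifiltration(cl, rep(2, 15), max_radius = 0.9)
  expect_true(all(bif0$vertex_grades[, 1] == 0))
  expect_true(all(bif0$edge_grades[, 1] == 0))
})

test_that("sparse large-ring edges enter at larger codensity than the dense small ring", {
  cl <- make_rings_dataset("2rings", 1, seed = 21)[[1]]
  f <- knn_codensity(cl, 5)
  large <- cl$labels == "ring1" # radius 2, 80 points: sparse
  small <- cl$labels == "ring2" # radius 0.7, 80 points: dense
  expect_gt(quantile(f[large], 0.05), quantile(f[small], 0.95))
  expect_gt(median(f[large]), 2 * median(f[small]))
})

test_that("diagonal restriction is the max-of-grades entry rule", {
  bif <- random_bifiltration(15, 42)
  off <- 0.3
  fc <- restrict_to_diagonal(bif, off)
  expect_equal(fc$edge_values,
               pmax(bif$edge_grades[, 1], bif$edge_grades[, 2] - off))
  # monotone from faces to cofaces (validated on construction, audit here)
  vmax <- pmax(fc$vertex_values[fc$edges[, 1]], fc$vertex_values[fc$edges[, 2]])
  expect_true(all(fc$edge_values >= vmax - 1e-12))
  # a line missing all grades clamps every simplex to the same start
  far <- restrict_to_diagonal(bif, -5)
  expect_true(all(far$vertex_values >= 5))
})
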