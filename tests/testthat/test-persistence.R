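test_that("unit square yields the analytic H1 bar [1, sqrt(2))", {
  fc <- build_rips_filtration(unit_square_cloud(), max_radius = 2)
  bc <- compute_barcode(fc)
  h1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  expect_equal(longest_bar(bc), sqrt(2) - 1)
  # H0: all four classes born at 0, one essential
  h0 <- bc[bc$dimension == 0, ]
  expect_equal(nrow(h0), 4L)
  expect_equal(sum(is.infinite(h0$death)), 1L)
})

test_that("n-gon loop births follow the chord-length formula", {
  cl <- regular_polygon_cloud(20, radius = 10)
  bc <- compute_barcode(build_rips_filtration(cl, max_radius = 25))
  h1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 2 * 10 * sin(pi / 20), tolerance = 1e-12)
})

test_that("equilateral triangle supports no H1 class", {
  cl <- regular_polygon_cloud(3)
  bc <- compute_barcode(build_rips_filtration(cl, max_radius = 3))
  expect_equal(sum(bc$dimension == 1), 0L) # triangle fills at its edge value
})

test_that("barcodes are additive over disjoint unions", {
  sq1 <- unit_square_cloud()$points
  sq2 <- sweep(sq1, 2, c(100, 100), "+")
  bc <- compute_barcode(build_rips_filtration(point_cloud(rbind(sq1, sq2)),
                                              max_radius = 2))
  h1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(h1), 2L)
  expect_equal(h1$birth, c(1, 1))
  expect_equal(h1$death, rep(sqrt(2), 2))
})

test_that("cohomology and naive reductions agree, under label shuffles too", {
  for (seed in 1:6) {
    cl <- with_test_seed(seed, point_cloud(cbind(runif(18), runif(18))))
    fc <- build_rips_filtration(cl, max_radius = 0.8)
    fast <- compute_barcode(fc)
    naive <- mphland:::cpp_barcode(fc$n_vertices, fc$vertex_values, fc$edges,
                                   fc$edge_values, fc$triangle_edges,
                                   fc$triangle_values, TRUE, TRUE,
                                   naive = TRUE)
    expect_equal(sorted_bars(fast, 1),
                 {
                   b <- data.frame(dimension = 1, birth = naive$h1_birth,
                                   death = naive$h1_death)
                   sorted_bars(b, 1)
                 },
                 ignore_attr = TRUE)
    # permuting vertex labels (a different tie-break) preserves the barcode
    perm <- with_test_seed(seed + 50, sample(18))
    fc2 <- build_rips_filtration(point_cloud(cl$points[perm, ]),
                                 max_radius = 0.8)
    expect_equal(sorted_bars(compute_barcode(fc2), 1), sorted_bars(fast, 1),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("lattice clouds with tied entry values reduce consistently", {
  # integer grid: heavy ties among distances
  g <- as.matrix(expand.grid(0:3, 0:3))
  bc1 <- compute_barcode(build_rips_filtration(point_cloud(g), 3))
  bc2 <- compute_barcode(build_rips_filtration(
    point_cloud(g[with_test_seed(99, sample(16)), ]), 3))
  expect_equal(sorted_bars(bc1, 1), sorted_bars(bc2, 1), ignore_attr = TRUE)
  expect_equal(sorted_bars(bc1, 0), sorted_bars(bc2, 0), ignore_attr = TRUE)
})

test_that("rank invariant at a = b is the Betti number", {
  bif <- random_bifiltration(12, 3)
  # at the top grade the full complex is present
  top <- c(2, 2)
  fc <- restrict_to_diagonal(bif, 0)
  bc <- compute_barcode(fc, dims = 1)
  alive <- sum(bc$birth <= 2 & (is.infinite(bc$death) | bc$death > 2))
  expect_equal(rank_invariant(bif, top, top, dim = 1), alive)
  # H0 at the top grade: number of components of the full complex
  expect_gte(rank_invariant(bif, top, top, dim = 0), 1L)
})

test_that("rank invariant is monotone and bounded by Betti numbers", {
  bif <- random_bifiltration(12, 5)
  a <- c(0.3, 0.4)
  bs <- list(c(0.4, 0.5), c(0.6, 0.7), c(0.9, 1.0))
  ranks <- vapply(bs, function(b) rank_invariant(bif, a, b), integer(1))
  expect_true(all(diff(ranks) <= 0)) # maps factor through larger grades
  beta_a <- rank_invariant(bif, a, a)
  expect_true(all(ranks <= beta_a))
  expect_error(rank_invariant(bif, c(0.5, 0.5), c(0.4, 0.6)), "coordinatewise")
})

test_that("rank invariant matches the diagonal-restriction barcode", {
  for (seed in c(2, 7)) {
    bif <- random_bifiltration(12, seed)
    off <- 0.15
    bc <- compute_barcode(restrict_to_diagonal(bif, off), dims = 1)
    for (pair in list(c(0.3, 0.6), c(0.4, 0.8), c(0.2, 0.4))) {
      u1 <- pair[1]; u2 <- pair[2]
      expected <- sum(bc$birth <= u1 &
                        (is.infinite(bc$death) | bc$death > u2))
      got <- rank_invariant(bif, c(u1, u1 + off), c(u2, u2 + off), dim = 1)
      expect_equal(got, expected)
    }
  }
})

test_that("barcode serialization round-trips including infinite bars", {
  bc <- compute_barcode(build_rips_filtration(unit_square_cloud(), 2))
  path <- tempfile(fileext = ".txt")
  write_barcode(bc, path)
  back <- read_barcode(path)
  expect_equal(sorted_bars(back, 0), sorted_bars(bc, 0), ignore_attr = TRUE)
  expect_equal(sorted_bars(back, 1), sorted_bars(bc, 1), ignore_attr = TRUE)
})

test_that("non-monotone filtrations are rejected", {
  expect_error(filtered_complex(2, c(0, 5), rbind(c(1L, 2L)), 1),
               "monotone")
})
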