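test_that("one-parameter landscapes follow the tent-function definition", {
  grid <- seq(0, 3, by = 0.25)
  # single bar: lambda(1) is its tent, lambda(2) vanishes
  L <- landscape_1d(cbind(0, 2), grid, k_max = 2)
  expect_equal(L[1, ], pmax(0, pmin(grid - 0, 2 - grid)))
  expect_equal(L[2, ], rep(0, length(grid)))
  # two identical bars: levels 1 and 2 coincide
  L2 <- landscape_1d(rbind(c(0, 2), c(0, 2)), grid, k_max = 2)
  expect_equal(L2[1, ], L2[2, ])
  # bars [0,2) and [1,3): second level at t = 1.5 is 0.5
  L3 <- landscape_1d(rbind(c(0, 2), c(1, 3)), 1.5, k_max = 2)
  expect_equal(L3[2, 1], 0.5)
  # infinite bar contributes t - birth
  L4 <- landscape_1d(cbind(1, Inf), c(2, 10), k_max = 1)
  expect_equal(L4[1, ], c(1, 9))
  expect_error(landscape_1d(cbind(0, 1), c(2, 1), 1), "sorted")
})

test_that("MPH landscape levels are ordered and diagonally 1-Lipschitz", {
  for (seed in c(1, 13)) {
    bif <- random_bifiltration(25, seed)
    L <- compute_mph_landscape(bif, grid_size = 12, k_max = 3)
    g <- 12
    for (k in 1:2) expect_true(all(L$values[k, , ] >= L$values[k + 1, , ]))
    expect_true(all(L$values >= 0))
    delta <- 1 / (g - 1)
    for (k in 1:3) {
      v <- L$values[k, , ]
      along <- abs(v[-1, -1] - v[-g, -g]) # adjacent points on a diagonal
      expect_true(all(along <= delta + 1e-12))
    }
  }
})

test_that("landscape equals the rank-invariant sup-h search exactly", {
  # small instances here; the full 50-cloud sweep runs in the acceptance suite
  for (seed in 1:4) {
    n <- with_test_seed(seed + 100, sample(8:12, 1))
    bif <- random_bifiltration(n, seed)
    L <- compute_mph_landscape(bif, grid_size = 6, k_max = 2)
    expect_lt(max(abs(L$values - oracle_landscape_grid(bif, 6, 2))), 1e-12)
  }
})

test_that("constant second parameter reproduces the 1-parameter landscape", {
  cl <- with_test_seed(5, point_cloud(cbind(runif(20), runif(20))))
  mr <- 0.9
  bif <- build_function_rips_bifiltration(cl, rep(1, 20), max_radius = mr)
  g <- 21
  L <- compute_mph_landscape(bif, grid_size = g, k_max = 2)
  bc <- compute_barcode(build_rips_filtration(cl, mr), dims = 1)
  bars <- cbind(bc$birth / mr, bc$death / mr)
  ref <- landscape_1d(bars, seq(0, 1, length.out = g), k_max = 2)
  # in the last column (x = 1) the landscape is min(x-room, 1d tent) = tent
  for (k in 1:2) {
    expect_equal(L$values[k, g, ], pmin(1, ref[k, ]), tolerance = 1e-12)
  }
})

test_that("landscapes are stable under small point perturbations", {
  cl <- with_test_seed(6, point_cloud(cbind(runif(40), runif(40))))
  f <- knn_codensity(cl, 5)
  mr <- 0.8
  eps <- 0.01 # 1% of the unit window
  bif1 <- build_function_rips_bifiltration(cl, f, mr, f_range = range(f))
  pert <- cl$points + matrix(with_test_seed(7, runif(80, -eps, eps)), ncol = 2)
  cl2 <- point_cloud(pert)
  # second-parameter values held fixed: isolate the Rips perturbation
  bif2 <- build_function_rips_bifiltration(cl2, f, mr, f_range = range(f))
  L1 <- compute_mph_landscape(bif1, 12, 2)
  L2 <- compute_mph_landscape(bif2, 12, 2)
  # moving each point by <= eps moves pairwise distances by <= 2 eps
  bound <- 2 * sqrt(2) * eps / mr
  expect_lt(max(abs(L1$values - L2$values)), bound + 1e-12)
})

test_that("landscape norms scale homogeneously and vanish at zero", {
  bif <- random_bifiltration(20, 2)
  L <- compute_mph_landscape(bif, 10, 2)
  zero <- L; zero$values[] <- 0
  expect_equal(landscape_norm(zero), 0)
  scaled <- L; scaled$values <- 3 * L$values
  expect_equal(landscape_norm(scaled, p = 2), 3 * landscape_norm(L, p = 2))
  expect_equal(landscape_norm(scaled, p = 1, levels = 1:2),
               3 * landscape_norm(L, p = 1, levels = 1:2))
  expect_error(landscape_norm(L, levels = 5), "k_max")
})

test_that("mean landscapes average pointwise and preserve level order", {
  bif <- random_bifiltration(18, 4)
  L <- compute_mph_landscape(bif, 8, 2)
  expect_equal(mean_landscape(list(L))$values, L$values)
  zero <- L; zero$values[] <- 0
  half <- mean_landscape(list(L, zero))
  expect_equal(half$values, L$values / 2)
  expect_true(all(half$values[1, , ] >= half$values[2, , ]))
  other <- compute_mph_landscape(bif, 9, 2)
  expect_error(mean_landscape(list(L, other)), "grid")
})

test_that("radius profiles integrate the first level over codensity", {
  bif <- random_bifiltration(18, 6)
  L <- compute_mph_landscape(bif, 10, 2)
  zero <- L; zero$values[] <- 0
  expect_equal(radius_profile(zero)$value, rep(0, 10))
  # constant landscape integrates to c * codensity range
  const <- L; const$values[] <- 2
  xr <- diff(L$axes$x_range)
  expect_equal(radius_profile(const)$value, rep(2 * xr, 10))
  expect_equal(radius_profile(L)$radius,
               seq(L$axes$y_range[1], L$axes$y_range[2], length.out = 10))
})

test_that("restricted radius integrals honor the cutoff", {
  bif <- random_bifiltration(18, 8)
  L <- compute_mph_landscape(bif, 10, 1)
  full <- landscape_norm(L, p = 1, units = "physical")
  expect_equal(restricted_radius_integral(L, radius_min = 0), full,
               tolerance = 1e-12)
  expect_warning(r <- restricted_radius_integral(L, radius_min = 10 *
                                                   L$axes$y_range[2]),
                 "beyond")
  expect_equal(r, 0)
  # supported entirely below the cutoff: zero
  low <- L
  low$values[, , 6:10] <- 0
  cutoff <- L$axes$y_range[2] * 0.55
  expect_equal(restricted_radius_integral(low, radius_min = cutoff), 0)
})
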