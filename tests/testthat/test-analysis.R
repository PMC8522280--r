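test_that("decay curves summarize replicates with mean and SD", {
  # strong chemotaxis so the macrophage ring has clearly collapsed by t = 8
  runs <- lapply(1:2, function(s) cached_abm_run(40, seed = s + 20,
                                                 duration = 8))
  cur <- decay_curves(runs, "longest_bar")
  expect_equal(dim(cur$values), c(2L, 3L))
  expect_equal(cur$mean, colMeans(cur$values))
  expect_true(all(cur$sd >= 0))
  # the macrophage ring shrinks: the longest bar decays from its start
  expect_lt(cur$mean[3], cur$mean[1])
  # a single replicate has zero SD
  one <- decay_curves(runs[1], "max_pcf")
  expect_equal(one$sd, rep(0, 3))
  expect_error(decay_curves(list(), "longest_bar"))
  expect_error(decay_curves(runs, "median_bar"))
})

test_that("landscape flattening is invertible and sized by levels", {
  Ls <- lapply(1:3, function(s)
    compute_mph_landscape(random_bifiltration(15, s), 7, 2))
  F1 <- flatten_landscapes(Ls, levels = 1)
  expect_equal(dim(F1), c(3L, 49L))
  F2 <- flatten_landscapes(Ls, levels = 1:2, labels = c("a", "a", "b"))
  expect_equal(dim(F2), c(3L, 98L))
  back <- unflatten_landscape(unclass(F2)[2, ], F2)
  expect_equal(back, Ls[[2]]$values[1:2, , ])
  expect_error(flatten_landscapes(Ls, labels = "a"), "one entry")
})

test_that("PCA separates distinct rows and accounts for all variance", {
  X <- rbind(matrix(0, 5, 20), matrix(1, 5, 20)) +
    with_test_seed(1, matrix(rnorm(200, 0, 0.01), 10, 20))
  F <- structure(X, labels = rep(c("lo", "hi"), each = 5),
                 class = c("feature_matrix", "matrix", "array"))
  p <- pca_project(F, 2)
  expect_equal(sum(p$variance_explained), 1)
  # the two classes separate along the first component
  expect_true(max(p$scores[1:5, 1]) < min(p$scores[6:10, 1]) ||
                min(p$scores[1:5, 1]) > max(p$scores[6:10, 1]))
  # degenerate input: all-equal rows give zero variance, no error
  pz <- pca_project(matrix(2, 4, 6), 2)
  expect_equal(pz$sdev, rep(0, 4), tolerance = 1e-12)
})

test_that("LDA protocol is at chance on exchangeable classes and perfect on separated ones", {
  with_test_seed(3, {
    same <- rbind(matrix(rnorm(300), 15, 20), matrix(rnorm(300), 15, 20))
    apart <- rbind(matrix(rnorm(300), 15, 20),
                   matrix(rnorm(300, mean = 8), 15, 20))
  })
  labs <- rep(c("a", "b"), each = 15)
  chance <- lda_protocol(same, labels = labs, repeats = 50, seed = 1)
  se <- stats::sd(chance$accuracies) / sqrt(50)
  expect_lt(abs(chance$mean_accuracy - 0.5), max(3 * se, 0.12))
  perfect <- lda_protocol(apart, labels = labs, repeats = 20, seed = 2)
  expect_equal(perfect$mean_accuracy, 1)
  expect_error(lda_protocol(same, labels = rep("a", 30), seed = 1))
  expect_error(lda_protocol(same[1:6, ], labels = labs[c(1:3, 16:18)],
                            seed = 1), "at least 5")
})

test_that("LDA accuracy tracks planted class separation", {
  labs <- rep(c("a", "b"), each = 12)
  accs <- vapply(c(0, 1.5, 6), function(delta) {
    X <- with_test_seed(40 + delta, rbind(matrix(rnorm(240), 12, 20),
                                          matrix(rnorm(240, delta), 12, 20)))
    lda_protocol(X, labels = labs, repeats = 30, seed = 3)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05)) # nondecreasing in effect size
  expect_gt(accs[3], accs[1] + 0.3)
})

test_that("permutation test hits its floor and flips with the side", {
  # groups large enough that no random permutation redraws the original
  # labeling (C(20,10) assignments), so the add-one floor is attained
  a <- 101:110
  b <- 1:10
  p <- permutation_test_means(a, b, n_perm = 99, side = "greater", seed = 1)
  expect_equal(p, 1 / 100) # the add-one floor
  p_rev <- permutation_test_means(b, a, n_perm = 99, side = "greater",
                                  seed = 1)
  expect_gt(p_rev, 0.95)
  p_less <- permutation_test_means(b, a, n_perm = 99, side = "less", seed = 1)
  expect_equal(p_less, 1 / 100)
  expect_error(permutation_test_means(numeric(0), b, seed = 1), "nonempty")
  expect_error(permutation_test_means(a, b, n_perm = 0, seed = 1))
})

test_that("permutation p-values are invariant under common affine maps", {
  with_test_seed(9, {
    a <- rnorm(12); b <- rnorm(12, 0.5)
  })
  p1 <- permutation_test_means(a, b, n_perm = 200, side = "two.sided",
                               seed = 5)
  p2 <- permutation_test_means(3 * a + 7, 3 * b + 7, n_perm = 200,
                               side = "two.sided", seed = 5)
  expect_equal(p1, p2)
})

test_that("bootstrap subsamples are sized, labeled and reproducible", {
  cl <- synth_tissue_scene(n_per_type = 400, seed = 1,
                           exclusion = c(CD8 = 0))
  subs <- bootstrap_subsamples(cl, n_samples = 5, size = 150, seed = 2)
  expect_length(subs, 5L)
  for (s in subs) {
    expect_equal(n_points(s), 150L)
    expect_equal(length(s$tissue), 150L)
    expect_false(any(duplicated(s$points))) # without replacement
  }
  again <- bootstrap_subsamples(cl, n_samples = 5, size = 150, seed = 2)
  expect_identical(subs, again)
  # size = |cloud| returns a permutation of the full cloud
  all_of_it <- bootstrap_subsamples(cl, n_samples = 1, size = 400, seed = 3)
  expect_equal(nrow(unique(all_of_it[[1]]$points)), 400L)
  expect_error(bootstrap_subsamples(cl, 1, size = 1000, seed = 1), "fewer")
})
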