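# Statistical layer: decay curves over ABM time series, landscape
# vectorization, PCA/LDA protocols, permutation tests and bootstrap
# subsampling.

# per-snapshot statistics available to decay_curves
snapshot_statistic <- function(cloud, statistic, settings) {
  switch(statistic,
    longest_bar = {
      fc <- build_rips_filtration(cloud, max_radius = settings$max_radius)
      longest_bar(compute_barcode(fc, dims = 1L), dim = 1L)
    },
    max_pcf = {
      max_pcf(pair_correlation(cloud, r_max = settings$r_max,
                               bin_width = settings$bin_width))
    },
    landscape_norm = {
      f <- knn_codensity(cloud, k = settings$codensity_k)
      bif <- build_function_rips_bifiltration(
        cloud, f, max_radius = settings$max_radius,
        f_range = settings$f_range)
      L <- compute_mph_landscape(bif, grid_size = settings$grid_size,
                                 k_max = settings$k_max)
      landscape_norm(L, p = 2, levels = settings$norm_levels)
    },
    stop("unknown statistic: ", statistic))
}

# shared settings with sensible defaults for ABM-scale clouds
decay_settings <- function(runs, settings = list()) {
  L <- runs[[1]]$params$domain_half %||% 14
  defaults <- list(max_radius = 1.3 * L, r_max = NULL, bin_width = NULL,
                   codensity_k = 5L, grid_size = 15L, k_max = 2L,
                   norm_levels = 1L, f_range = NULL)
  defaults[names(settings)] <- settings
  if (is.null(defaults$f_range)) {
    # One common codensity normalization across all clouds of the analysis,
    # so landscape norms are comparable across time, replicates and matched
    # clean/noisy groups. As in codensity_landscapes(), the range covers
    # the bulk of the codensity distribution (80th percentile + headroom):
    # sparse mislabeled cells lie in the upper tail and enter the
    # filtration beyond the parameter rectangle.
    q <- max(unlist(lapply(runs, function(r)
      lapply(r$clouds, function(cl)
        quantile(knn_codensity(cl, defaults$codensity_k), 0.8)))))
    defaults$f_range <- c(0, 1.15 * q)
  }
  defaults
}

#' Decay curves of a per-snapshot statistic over replicate runs
#'
#' Computes the chosen statistic (longest H1 bar, maximum of the PCF, or
#' the 2-norm of the first MPH landscape of the radius-codensity
#' bifiltration) for every observation of every replicate run, and returns
#' mean and standard-deviation curves across replicates.
#'
#' For `landscape_norm` the codensity axis is normalized with one common
#' range across all clouds of the analysis (computed from the data unless
#' supplied via `settings$f_range`), so values are comparable across time
#' and between matched analyses.
#'
#' @param runs list of `abm_run` objects with aligned observation times.
#' @param statistic `"longest_bar"`, `"max_pcf"` or `"landscape_norm"`.
#' @param settings named list overriding the analysis settings
#'   (`max_radius`, `grid_size`, `k_max`, `codensity_k`, `f_range`,
#'   `norm_levels`, `r_max`, `bin_width`).
#' @return a `summary_curve`: list with `statistic`, `times`, the
#'   replicate-by-time `values` matrix, `mean` and `sd` curves.
#' @export
decay_curves <- function(runs, statistic = c("longest_bar", "max_pcf",
                                             "landscape_norm"),
                         settings = list()) {
  statistic <- match.arg(statistic)
  if (length(runs) < 1L) stop("need at least one replicate run")
  times <- runs[[1]]$times
  for (r in runs) {
    if (!isTRUE(all.equal(r$times, times)))
      stop("replicate observation times are not aligned")
  }
  settings <- decay_settings(runs, settings)
  values <- t(vapply(runs, function(r) {
    vapply(r$clouds, snapshot_statistic, numeric(1),
           statistic = statistic, settings = settings)
  }, numeric(length(times))))
  structure(list(statistic = statistic, times = times, values = values,
                 mean = colMeans(values),
                 sd = if (nrow(values) > 1L) apply(values, 2, stats::sd)
                      else rep(0, ncol(values)),
                 settings = settings),
            class = "summary_curve")
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary_curve (%s): %d replicates x %d times; mean %.4g -> %.4g\n",
              x$statistic, nrow(x$values), length(x$times),
              x$mean[1], x$mean[length(x$mean)]))
  invisible(x)
}

#' Noise-disruption metric of a decay statistic
#'
#' Quantifies how much misclassification noise disturbs a decay curve:
#' `d = mean_t |clean(t) - noisy(t)| / max_t clean(t)`, the normalized L1
#' distance between the clean and noisy mean curves. Smaller is more
#' robust. Clean and noisy runs should be matched (same simulations), and
#' the same analysis settings (including the codensity normalization
#' range) are used for both.
#'
#' @param clean_runs,noisy_runs lists of matched `abm_run` objects.
#' @param statistic as in [decay_curves()].
#' @param settings as in [decay_curves()]; a common `f_range` is computed
#'   over both groups when not supplied.
#' @return list with `d`, and the two `summary_curve`s.
#' @export
noise_disruption <- function(clean_runs, noisy_runs,
                             statistic = c("longest_bar", "max_pcf",
                                           "landscape_norm"),
                             settings = list()) {
  statistic <- match.arg(statistic)
  settings <- decay_settings(c(clean_runs, noisy_runs), settings)
  clean <- decay_curves(clean_runs, statistic, settings)
  noisy <- decay_curves(noisy_runs, statistic, settings)
  d <- mean(abs(clean$mean - noisy$mean)) / max(clean$mean)
  list(d = d, clean = clean, noisy = noisy)
}

#' Flatten MPH landscapes into a feature matrix
#'
#' Row-major flattening: for each selected level in order, the landscape
#' values are appended with the x (second-parameter) index varying fastest.
#' The inverse is [unflatten_landscape()].
#'
#' @param Ls list of `mph_landscape` objects on a common grid.
#' @param levels landscape levels to include (default 1).
#' @param labels optional per-landscape class labels.
#' @return a `feature_matrix`: numeric matrix with one row per landscape,
#'   with attributes `labels`, `levels` and `grid`.
#' @export
flatten_landscapes <- function(Ls, levels = 1L, labels = NULL) {
  if (length(Ls) == 0L) stop("need at least one landscape")
  g <- dim(Ls[[1]]$values)
  rows <- lapply(Ls, function(L) {
    if (!identical(dim(L$values), g)) stop("landscape grids do not match")
    unlist(lapply(levels, function(k) as.numeric(L$values[k, , ])))
  })
  X <- do.call(rbind, rows)
  if (!is.null(labels) && length(labels) != nrow(X))
    stop("labels must have one entry per landscape")
  structure(X, labels = labels, levels = levels,
            grid = list(nx = g[2], ny = g[3],
                        x_grid = Ls[[1]]$x_grid, y_grid = Ls[[1]]$y_grid,
                        axes = Ls[[1]]$axes),
            class = c("feature_matrix", "matrix", "array"))
}

#' Reshape a feature vector back into landscape arrays
#'
#' @param v numeric vector as produced by [flatten_landscapes()] (one row).
#' @param F the `feature_matrix` carrying the grid metadata.
#' @return array `length(levels) x nx x ny`.
#' @export
unflatten_landscape <- function(v, F) {
  grid <- attr(F, "grid")
  levels <- attr(F, "levels")
  aperm(array(v, dim = c(grid$nx, grid$ny, length(levels))), c(3, 1, 2))
}

#' Principal component analysis of landscape feature vectors
#'
#' Centered PCA of a feature matrix; component vectors can be reshaped to
#' landscape grids with [unflatten_landscape()] for visualization.
#'
#' @param F a `feature_matrix` (or plain matrix) with at least 2 rows.
#' @param n_components number of components to return.
#' @return list with `scores`, `components` (columns), `sdev`,
#'   `variance_explained` and the input labels.
#' @export
pca_project <- function(F, n_components = 2L) {
  X <- unclass(F)
  attributes(X)[c("labels", "levels", "grid", "class")] <- NULL
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(nc), drop = FALSE],
       components = p$rotation[, seq_len(nc), drop = FALSE],
       sdev = p$sdev,
       variance_explained = p$sdev^2 / max(sum(p$sdev^2), .Machine$double.eps),
       labels = attr(F, "labels"))
}

# regularized LDA direction by shrinkage toward a scaled identity,
# computed via the Woodbury identity so that wide feature matrices
# (d >> n) stay cheap
rlda_fit <- function(X0, X1, gamma) {
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  Xc <- rbind(sweep(X0, 2, mu0), sweep(X1, 2, mu1))
  n <- nrow(Xc)
  denom <- max(n - 2L, 1L)
  sigma2 <- sum(Xc^2) / (ncol(Xc) * denom)
  if (sigma2 <= 0) sigma2 <- 1 # degenerate: identical rows; any direction
  delta <- mu1 - mu0
  alpha <- gamma * sigma2
  cc <- (1 - gamma) / denom
  G <- Xc %*% t(Xc)
  M <- diag(alpha, n) + cc * G
  v <- as.numeric(Xc %*% delta)
  w <- (delta - cc * as.numeric(crossprod(Xc, solve(M, v)))) / alpha
  thr <- sum(w * (mu0 + mu1)) / 2
  list(w = w, threshold = thr)
}

#' Repeated-split regularized LDA classification protocol
#'
#' For a pair of classes: make a stratified randomized 80/20 training/test
#' split, train a shrinkage-regularized linear discriminant classifier on
#' the training rows, evaluate accuracy on the test rows, and repeat. The
#' pooled within-class covariance is shrunk toward a scaled identity,
#' `S_reg = (1 - gamma) S + gamma mean(diag(S)) I`, which keeps the
#' discriminant well defined when the feature dimension exceeds the sample
#' count.
#'
#' @param F a `feature_matrix` with a `labels` attribute (or a plain
#'   matrix plus `labels`).
#' @param classes length-2 character vector naming the pair of classes;
#'   defaults to the two classes present (error if not exactly two).
#' @param labels optional labels overriding `attr(F, "labels")`.
#' @param split training fraction (default 0.8).
#' @param repeats number of random splits (default 100).
#' @param gamma shrinkage strength in (0, 1\] (default 0.5).
#' @param seed integer seed; split r uses a seed derived from it.
#' @return list with `mean_accuracy`, per-repeat `accuracies`, `classes`.
#' @export
lda_protocol <- function(F, classes = NULL, labels = attr(F, "labels"),
                         split = 0.8, repeats = 100L, gamma = 0.5, seed) {
  X <- unclass(F)
  attributes(X)[c("labels", "levels", "grid", "class")] <- NULL
  if (is.null(labels)) stop("class labels are required")
  labels <- as.character(labels)
  if (is.null(classes)) {
    classes <- unique(labels)
    if (length(classes) != 2L)
      stop("specify `classes`: found ", length(classes), " classes")
  }
  if (length(unique(classes)) != 2L) stop("`classes` must name two classes")
  i0 <- which(labels == classes[1]); i1 <- which(labels == classes[2])
  if (length(i0) < 5L || length(i1) < 5L)
    stop("each class needs at least 5 rows")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  acc <- vapply(seq_len(repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      tr0 <- sample(i0, max(1L, round(split * length(i0))))
      tr1 <- sample(i1, max(1L, round(split * length(i1))))
      te0 <- setdiff(i0, tr0); te1 <- setdiff(i1, tr1)
      if (length(te0) == 0L) { te0 <- tr0[1]; tr0 <- tr0[-1] }
      if (length(te1) == 0L) { te1 <- tr1[1]; tr1 <- tr1[-1] }
      fit <- rlda_fit(X[tr0, , drop = FALSE], X[tr1, , drop = FALSE], gamma)
      sc <- as.numeric(X[c(te0, te1), , drop = FALSE] %*% fit$w)
      pred <- ifelse(sc > fit$threshold, classes[2], classes[1])
      mean(pred == c(rep(classes[1], length(te0)),
                     rep(classes[2], length(te1))))
    })
  }, numeric(1))
  list(mean_accuracy = mean(acc), accuracies = acc, classes = classes)
}

#' One- or two-sided permutation test for a difference of means
#'
#' Label-permutation null for the difference `mean(group_a) -
#' mean(group_b)`, with the add-one correction `p = (1 + #{extreme}) /
#' (n_perm + 1)`.
#'
#' @param group_a,group_b numeric vectors (nonempty).
#' @param n_perm number of permutations (>= 1).
#' @param side `"greater"` (mean of A exceeds mean of B), `"less"`, or
#'   `"two.sided"`.
#' @param seed integer seed.
#' @return the p-value.
#' @export
permutation_test_means <- function(group_a, group_b, n_perm = 1000L,
                                   side = c("greater", "less", "two.sided"),
                                   seed) {
  side <- match.arg(side)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- mean(group_a) - mean(group_b)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  extreme <- switch(side,
    greater = sum(perm >= obs),
    less = sum(perm <= obs),
    two.sided = sum(abs(perm) >= abs(obs)))
  (1 + extreme) / (n_perm + 1)
}

#' Bootstrap subsamples of a large point cloud
#'
#' Uniform subsamples without replacement (independent across samples),
#' carrying labels and tissue categories along; the device used to keep
#' MPH computations tractable on large clouds (study scale: 50 subsamples
#' of 1,500 points).
#'
#' @param cloud a [point_cloud()] with at least `size` points.
#' @param n_samples number of subsamples (default 50).
#' @param size points per subsample (default 1500).
#' @param seed integer seed.
#' @return list of [point_cloud()] objects.
#' @export
bootstrap_subsamples <- function(cloud, n_samples = 50L, size = 1500L,
                                 seed) {
  n <- n_points(cloud)
  if (n < size) stop("cloud has fewer than `size` points")
  lapply(seq_len(n_samples), function(i) {
    idx <- with_seed(derive_seed(seed, i), sample.int(n, size))
    cloud_subset(cloud, idx)
  })
}
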