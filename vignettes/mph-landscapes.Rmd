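---
title: "Multiparameter persistence landscapes for cell point patterns: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparameter persistence landscapes for cell point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mphland)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, every tunable parameter that matters,
what the synthetic generators do and do not emulate, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. From point clouds to bifiltrations

The input throughout is a `point_cloud`: 2D cell centers (micrometers for
histology, cell diameters for simulations) with optional per-point cell
type and tissue category. Spatial structure is probed with a *bifiltered*
Vietoris–Rips complex, `build_function_rips_bifiltration()`: a simplex
(up to dimension 2) enters at the grade

* y — its Rips entry value, with the **diameter convention**: an edge
  enters at the distance between its endpoints, i.e. when balls of
  *radius y/2* drawn at the points touch. Users converting from a
  ball-radius convention should divide by 2.
* x — the largest second-parameter value of its vertices, where the
  second parameter is either the **codensity** (`knn_codensity()`,
  distance to the k-th nearest neighbor, default k = 5; large = sparse)
  or the **hypoxia ordinal** (`tissue_ordinal()`: Stroma 0, PanCK 1,
  CAIX 2, Pimo 3, Necrosis 4, so the best-oxygenated cells are admitted
  first, mirroring codensity).

Filtering by codensity admits dense regions first: outlier cells — for
instance tumor cells mislabeled as macrophages by an imaging pipeline —
enter only at large x, so topological features that need them are pushed
to a corner of the parameter plane instead of corrupting every scale, the
failure mode of single-parameter persistence.

Both axes are affinely normalized onto [0, 1] so that they vary over
similar scales: the radius axis by `[0, max_radius]`, the codensity axis
by `f_range`. The scale factors are kept in the axis metadata and all
landscape values are reported in normalized units (a diagonal direction
mixes the two physical units, so a "physical" landscape value has no
single unit); quadratures can be taken in physical axis units where that
is meaningful (`radius_profile()`, `restricted_radius_integral()`,
`landscape_norm(units = "physical")`).

**Choice of `max_radius`.** Features that die beyond `max_radius` appear
as infinite bars, so `max_radius` should exceed the death scale
√3·R of the largest ring-like feature of radius R one wants resolved. The
cost driver is the number of Rips triangles, which grows steeply with
`max_radius`; the defaults used by the analyses in this package (3.6
length units for the ring fixtures, 25 cell diameters for ABM macrophage
clouds, 600 μm for 1.5 mm histology regions) are the smallest values that
cover the relevant deaths with margin.

**Choice of `f_range`.** For any *comparative* analysis (decay curves,
PCA, classification) one common `f_range` must be used for every cloud,
otherwise norms are not comparable. The package default for batch
analyses (`codensity_landscapes()`, `decay_curves()`) is the robust range
`[0, 1.15 × max over clouds of the 80th codensity percentile]`. The
rectangle then covers the bulk of the codensity distribution while the
sparse outlier tail enters beyond it — which is precisely the role the
codensity parameter is meant to play. With the full data range instead,
the handful of outliers stretches the axis, spurious outlier-born loops
acquire landscape mass, and the robustness advantage of the
two-parameter approach is lost; both behaviours are exercised in the test
suite. The quantile (0.8) matches the design of the ring fixtures (80
ring points : 20 outliers); for data with a heavier contamination rate it
should be lowered accordingly, and `f_range` can always be fixed
explicitly.

## 2. Persistence computation

All homology is over Z₂. `compute_barcode()` reduces H0 by a union-find
pass with the elder rule, and H1 pairs by a **persistent cohomology**
reduction of the edge coboundary matrix in reverse filtration order with
clearing (negative edges, already pivots of the dimension-0 coboundary,
are skipped), a lazy heap working column, and implicit columns for edges
that claim their pivot without additions — the zero-persistence
"apparent" pairs that dominate Rips filtrations. The number of columns
scales with edges rather than triangles, which makes dense slices
tractable. The textbook triangle-by-triangle boundary reduction is
retained behind a `naive` flag as the reference implementation; the test
suite asserts both paths produce identical barcodes, and that barcodes
are invariant under relabeling of tied simplices (ties are broken by
dimension, then lexicographic vertex order). Zero-length bars are
discarded; essential classes are reported with `death = Inf`.

## 3. MPH landscapes by diagonal slicing

`compute_mph_landscape()` evaluates λ(k, x⃗) on a square g × g grid over
the normalized unit square. The production path restricts the
bifiltration to the diagonal lines y = x + offset through the grid
anti-diagonals: on such a line, a simplex with grade (a, b) enters at
u = max(a, b − offset), the restriction is an ordinary filtration, and
the k-th tent value of its barcode at u *equals* the sup-h rank
expression — exactly, with no interpolation, because every grid point
lies on exactly one chosen line. Per slice, the triangle order is
produced by an O(t) filtered merge of two precomputed per-axis orders
rather than a fresh sort.

The equality with the definition is enforced in the test suite against an
independent oracle: `rank_invariant()` computes rank(H(K_a) → H(K_b)) by
explicit Z₂ linear algebra on cycle and boundary spaces
(rank [Z_a | B_b] − rank B_b), and a bisection over the critical values
of h recovers λ(k, x⃗) without ever touching the reduction code. On
random clouds the two paths agree to double-rounding precision
(≤ 2 ulp).

Grid resolution is the accuracy knob for every landscape-derived
quadrature (norms, radius profiles, restricted integrals, feature
vectors) and is recorded in the returned object. The package's own
analyses use 15 × 15 for the ring fixtures and ABM decay curves — the
features there span large fractions of the parameter rectangle, and the
statistics of interest (norm ratios, mass locations, separability) are
stable under refinement — and the constructor default of 60 × 60 for
1.5 mm histology regions.

Known limitation: only one-critical bifiltrations (function-Rips) are
supported, homology dimension 1 is the focus (H0 available for testing),
and multi-critical or degree-Rips constructions are out of scope.

## 4. Ring fixtures

`make_rings_dataset()` draws the two cloud families used to demonstrate
the method: each ring carries 80 points uniform on the circle with radial
Gaussian jitter (sd = 5% of the radius) plus 20 outliers uniform in the
enclosed open disk.

* `"3rings"`: three radius-1.5 rings at the vertices of an equilateral
  triangle of side 7.2. The spacing is deliberately wider than
  `max_radius` = 3.6: were the rings close enough to connect below the
  truncation scale, the central gap between them would bound a *fourth*
  persistent loop, and the defining property of this family — signal in
  landscape levels 1–3 and essentially none in level 4 — would fail for
  a geometric reason, not a statistical one.
* `"2rings"`: one radius-2 ring and one radius-0.7 ring, centers 5
  apart. Both carry 80 points, so the large ring is sparsely and the
  small ring densely sampled; the large loop therefore lives at large
  radius *and* large codensity.

Replicate r of a dataset uses the derived seed
`(seed·1000003 + r) mod (2³¹−1)`; identical seeds reproduce bit-identical
clouds. The fixtures emulate controlled loop structure with outlier
contamination; they do not emulate anisotropy, intensity gradients, or
the hard-core repulsion of real cell centers, so passing tests on them
demonstrates sensitivity to loop size/count and outlier robustness, not
performance on arbitrary tissue.

## 5. The agent-based model

`run_abm()` is a 2D off-lattice cell-center model of macrophage
infiltration into an avascular spheroid. Lengths are in cell diameters
(= 1), time in simulation units; all parameters live in `abm_params()`
and are the package's own documented choices.

* **Mechanics.** Overdamped position updates under pairwise linear
  springs: repulsion below the rest length 1, adhesion tapering to zero
  at the interaction radius 1.5, stiffness 8, drag 1, dt = 0.05 (the
  pair relaxation factor 2·k·dt = 0.8 < 1 keeps the explicit update
  stable).
* **Oxygen.** Quasi-steady diffusion with a linear sink proportional to
  the local viable-cell density (`solve_quasi_steady_field()`, Dirichlet
  boundary value 1): ∇·(D∇c) − κρc = 0 with D = 100, κ = 3. The
  penetration depth √(D/κρ) ≈ 5.4 produces, for an equilibrium spheroid
  of radius ≈ 12, a necrotic core of radius ≈ 6 and a hypoxic band deep
  in the viable shell.
* **Cell rules.** Ordered thresholds 0.3 < 0.5 < 0.7: below 0.3 a
  viable cell's hypoxia clock runs (necrosis after 4 time units,
  one-way); below 0.5 viable cells secrete CSF-1; above 0.7, cells with
  at most 4 neighbors within 1.2 divide at rate 0.1 per time unit.
  Necrotic cells are inert obstacles and are retained (a removal rate is
  available, default 0).
* **CSF-1.** Quasi-steady with zero-flux boundary, D = 20, decay 0.4,
  secretion 1 per unit hypoxic density. The decay length √(20/0.4) ≈ 7
  makes the field peak interior to the secreting band, so the
  chemotactic force χ·∇c pulls macrophages *past* the band toward the
  core; with a shorter decay length they stall at the band, which is the
  main calibration failure mode.
* **Fields** are re-solved every 4 time units and frozen in between
  (diffusion is fast relative to cell motion, the standard hybrid-model
  assumption); each solve is a sparse direct solve with residual checked
  below 1e-8 of the source norm.
* **Initialization.** `initialize_spheroid()` burns in a hexagonally
  packed disc (radius 12) without macrophages until the *viable* cell
  count changes by < 2% over 50 consecutive steps (checked only after
  the first necrosis wave can have occurred). Stationarity of the viable
  count is the operational meaning of "proliferation balances death":
  with necrotic cells retained the total count cannot equilibrate, but
  the living compartment does. Then 100 macrophages are placed at
  uniform random angles, touching the local spheroid boundary, and the
  clock is set to t = 0.
* **Observation.** Macrophage coordinates every 4 time units for 100
  units: 26 observations. `observe_with_noise()` produces the matched
  noisy observations by mislabeling every tumor cell (viable or
  necrotic) as a macrophage with probability 0.01, per observation.

With these defaults the chemotactic sensitivities χ = 10, 20, 40 give
infiltration half-times (first time the mean macrophage distance to the
spheroid centroid halves, `infiltration_half_time()`) of roughly 43, 14
and 10 time units at the reference seed, and χ = 0 shows no infiltration;
the monotone trend over replicates is asserted in the acceptance suite.
The reduced spheroid (≈ 500 tumor cells) keeps full runs at a few seconds
each; it also means p = 0.01 injects ≈ 5 false cells per snapshot rather
than the ≈ 20 a full-size spheroid would give, so noise-robustness
comparisons are direction-based, not magnitude-based. The model makes no
claim to reproduce any particular laboratory parameterization: vasculature,
macrophage phenotype switching and 3D effects are all absent.

## 6. Baselines and statistics

* `pair_correlation()`: Ripley-style annulus histogram of pairwise
  distances with the **translation** edge correction
  w = |W| / ((W_x−|dx|)(W_y−|dy|)), which is closed-form and exactly
  unbiased on rectangular windows (complete spatial randomness gives
  E[g] = 1, verified by Monte-Carlo calibration). Defaults: bin width =
  shorter window side / 50, r_max = side / 4. `max_pcf()` is the scalar
  summary.
* `decay_curves()` evaluates longest bar, max g(r), or the landscape
  2-norm per observation per replicate and returns mean ± SD curves;
  `noise_disruption()` compares matched clean/noisy runs through
  d = mean_t |clean−noisy| / max_t clean, computed with identical
  settings (including the shared codensity range) for both groups.
* `lda_protocol()`: stratified randomized 80/20 splits, a linear
  discriminant with the pooled covariance shrunk toward a scaled
  identity, S_γ = (1−γ)S + γ·mean(diag S)·I (default γ = 0.5, exposed),
  applied via the Woodbury identity so that landscape-sized feature
  vectors (d ≫ n) cost only an n × n solve per split; mean test accuracy
  over 100 repeats. Under the null, accuracy for a single fixed dataset
  scatters widely around 1/2 (slightly pessimistically, as is well known
  for cross-validation under exchangeability), so chance-level
  calibration should average over independent datasets.
* `permutation_test_means()`: label permutations of the difference of
  means with the add-one correction; one- or two-sided. Type-I error is
  calibrated in the acceptance suite.
* `bootstrap_subsamples()`: uniform subsamples without replacement (50 ×
  1,500 by default), the device that keeps MPH computations tractable on
  clouds of ~10⁴ cells.
* `sample_rois()`: nonoverlapping 1.5 mm squares placed greedily at
  random inside a polygonal mask until 10,000 consecutive rejections
  (saturation), or on a regular grid; whether real studies place regions
  randomly or grid-aligned is unknowable from published methods, hence
  the switch. ROI coordinates are lower-left-origin with y increasing
  upward.

## 7. Numerical conventions and degenerate inputs

Ties among equal entry values are broken by dimension then lexicographic
vertex order (deterministic, and provably irrelevant to the barcode).
Coincident points are legal (codensity 0; coincident ABM cells are pushed
apart along a fixed axis). Empty clouds, empty barcodes, single-replicate
decay curves (SD 0), zero landscapes and degenerate PCA inputs
(zero variance) all return well-defined values rather than errors; the
`restricted_radius_integral()` cutoff is inclusive (≥), and a cutoff
beyond the grid returns 0 with a warning. Landscape norms and integrals
use trapezoidal quadrature on the landscape grid.

## 8. What the acceptance script computes

`scripts/acceptance.R --seed S --out F` re-runs, from scratch: the
landscape/oracle agreement rate (50 random clouds), the ring-fixture
statistics (norm ratio ‖λ₃‖/‖λ₄‖, large-radius mass ratio, linear
separability of the 60 feature vectors), the ABM observation count,
Spearman trend of infiltration half-time in χ (15 runs), the
noise-disruption metrics for both decay statistics, CSR calibration of
the PCF, the permutation-test type-I error at α = 0.05, and the LDA
protocol's chance-level and separated-class accuracies. Every random
draw derives from `--seed`.
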