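# mphland

Multiparameter persistent homology (MPH) landscapes for 2D cell point
patterns.

## The problem

Digitized histology reduces a tissue section to a point cloud of cell
centers with categorical labels (cell type, and sometimes an ordinal
hypoxia category). Quantifying the *spatial architecture* of such clouds —
rings of macrophages around a tumor spheroid, voids left by immune cells
around necrotic cores — is hard for classical spatial statistics and for
single-parameter persistent homology (1-PH) alike: the pair-correlation
function g(r) cannot tell a peripheral ring from a central cluster, and
1-PH is notoriously fragile to the misclassified cells that every image
analysis pipeline produces.

`mphland` implements the two-parameter alternative. A point cloud is
filtered simultaneously by a **Vietoris–Rips radius** parameter
y (which detects the *size* of topological features) and by a
**codensity** parameter x (distance to the k-th nearest neighbor, k = 5 by
default), which admits cells from dense regions first and thereby
suppresses sparse outliers. The same machinery accepts an ordinal
**hypoxia** value (Stroma < PanCK < CAIX < Pimo < Necrosis) as the second
parameter. The resulting bifiltration is summarized by **MPH landscapes**

λ(k, x⃗) = sup { h ≥ 0 : rank( H₁(K_{x⃗−h(1,1)}) → H₁(K_{x⃗+h(1,1)}) ) ≥ k },

the prominence of the k-th most prominent loop at parameter x⃗ = (x, y).
Landscapes are computed exactly by slicing the bifiltration along the
diagonal lines through the grid (each slice is an ordinary Z₂ persistence
computation, done in compiled code via a coboundary reduction with
clearing), and are vectorizable: the package provides their norms, means,
radius profiles, restricted radius integrals, PCA/LDA classification
protocols, permutation tests and bootstrap subsampling — plus the
1-PH longest-bar and pair-correlation baselines, synthetic ring fixtures,
and an off-lattice cell-center agent-based model (ABM) of macrophage
infiltration into an avascular tumor spheroid under CSF-1 chemotaxis.

## Worked example

Two families of noisy ring clouds — three medium loops versus one large
sparse and one small dense loop, each ring carrying 80 points plus 20
enclosed outliers — are distinguishable by their landscapes but not by
counting cells:

```r
library(mphland)

rings3 <- make_rings_dataset("3rings", n_replicates = 30, seed = 101)
rings2 <- make_rings_dataset("2rings", n_replicates = 30, seed = 202)
L <- codensity_landscapes(c(rings3, rings2), k = 5, max_radius = 3.6,
                          grid_size = 15, k_max = 4)

norms <- sapply(L[1:30], function(l)
  sapply(1:4, function(k) landscape_norm(l, levels = k)))
round(rowMeans(norms), 4)
#> [1] 0.0349 0.0240 0.0142 0.0002
```

The three-ring clouds carry signal in landscape levels 1–3 and essentially
none in level 4 (three loops of the same scale; mean ‖λ(3)‖/‖λ(4)‖ ≈ 61),
while the two-ring clouds leave λ(1) mass at large radius parameters:

```r
mean(sapply(L[31:60], restricted_radius_integral, radius_min = 2.6))
#> [1] 0.0041   # two-ring family: the large loop lives at radius > 2.6
mean(sapply(L[1:30],  restricted_radius_integral, radius_min = 2.6))
#> [1] 5.2e-06  # three-ring family: nothing that large
```

Treated as feature vectors, the 60 first landscapes are 100% linearly
separable, and the repeated 80/20 regularized-LDA protocol classifies the
two families with mean accuracy 1.00:

```r
F <- flatten_landscapes(L, levels = 1,
                        labels = rep(c("3rings", "2rings"), each = 30))
lda_protocol(F, repeats = 100, seed = 8)$mean_accuracy
#> [1] 1
```

The ABM side of the pipeline simulates macrophages infiltrating a tumor
spheroid and shows the robustness argument for MPH: under 1% tumor-cell
misclassification, the decay of the longest 1-PH bar is disrupted three to
five times more than the decay of the MPH landscape 2-norm
(`noise_disruption()`), while infiltration speed increases monotonically
with the chemotactic sensitivity χ (`infiltration_half_time()`).

A thin command-line wrapper over these functions ships in
`inst/cli/mph.R` (subcommands `make-rings`, `simulate-abm`, `landscape`,
`pcf`, `decay-curves`, `classify`, `permtest`, `rois`).

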