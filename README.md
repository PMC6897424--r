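# hodgescore

Clustering-independent feature selection on point clouds with
combinatorial Laplacian scores on simplicial complexes.

## The problem

Many genomic data sets — single-cell RNA-seq above all — have no true
replicates and often no stable clusters: cells sit on continuous
trajectories, loops (cell cycle, convergent differentiation) and spatial
gradients. Classical differential-expression tests need predefined groups;
ranking genes by variance ignores the metric structure entirely.

`hodgescore` ranks features (gene expression, pixel intensities, mutation
indicators, population memberships) by their consistency with the
*topology* of the data. The data enter as a sample-by-sample dissimilarity
matrix; a Vietoris–Rips clique complex at scale ε (edge *(i, j)* iff
*d(i, j) ≤ ε*, triangles = 3-cliques) — or an externally built complex such
as a Mapper nerve — represents the shape of the point cloud.

## The scores

Let ∂₁, ∂₂ be the signed boundary operators of the oriented complex,
*S* the edge weights, *D₀* the vertex degrees, *L₀ = ∂₁ S ∂₁ᵀ* and
*L₁ = ∂₁ᵀ∂₁ + ∂₂∂₂ᵀ* the combinatorial Hodge Laplacians.

* **R(0)** — for a vertex feature *f*, with degree-weighted centering *f̃*:

  R(0) = Σₑ Sₑ (f̃ᵤ − f̃ᵥ)² / (f̃ᵀ D₀ f̃)

  This is exactly the He–Cai–Niyogi Laplacian score of the 1-skeleton: low
  values = feature localized on densely connected regions.

* **R(1)** — for an edge cochain *g* (a vertex feature lifted by endpoint
  averaging): the Rayleigh quotient *gᵀL₁g / gᵀg*. It is zero iff *g* is
  harmonic, i.e. aligned with a non-contractible loop; low values flag
  features expressed along cycles of the expression space.

* **R(0) bivariate** — a covariance-like cross score for feature pairs;
  negative values flag pairs occupying adjacent but non-overlapping
  regions (e.g. neighboring tissue layers).

Significance is assessed by permuting vertex labels (shared permutation
set, one-sided low tail, add-one estimator, so p > 0), with
Benjamini–Hochberg FDR across features. The scale ε is chosen by
maximizing the number of BH rejections over a grid — degenerate scales
(no edges, or the complete graph) reject nothing by construction.

## Worked example

A noisy circle with an arc-localized indicator and a smooth wave:

```r
library(hodgescore)

sim <- simulate_circle(n_points = 100, noise_sd = 0.05, seed = 1)
d   <- compute_distance_matrix(sim$coords, "euclidean")
cx  <- build_vietoris_rips(d, epsilon = 0.26)
cx
#> Simplicial complex: 100 vertices, 349 edges, 480 triangles (epsilon = 0.26)
betti_numbers(cx)
#> b0 b1
#>  1  1

features <- rbind(arc  = sim$arc_feature,
                  wave = 1 + 0.5 * sin(2 * pi * (1:100) / 100))
colnames(features) <- rownames(sim$coords)
cfg <- inference_config(n_perm = 999, seed = 2)

score_table(cx, features, q = 0, config = cfg)
#>  feature_id q      score p_value q_value
#>        wave 0 0.01415939   0.001   0.001
#>         arc 0 0.12442068   0.001   0.001

score_table(cx, features, q = 1, config = cfg)
#>  feature_id q    score p_value q_value
#>        wave 1 2.912228   0.206   0.206
#>         arc 1 3.006173   0.008   0.016
```

The complex has one connected component and one loop (`b0 = 1, b1 = 1`).
Both features localize strongly at dimension 0 (small scores, p = 0.001,
the resolution floor of 999 permutations). At dimension 1 the two
features separate by score and significance in the lifted edge
representation. Constant features are reported as `NA` score with
p = 1 rather than failing.

A shell interface wraps the same pipeline:

```sh
Rscript exec/hodgescore simulate --preset two-pop --seed 1 --out-dir sim/
Rscript exec/hodgescore select-epsilon --features sim/counts.mtx ... --eps-grid 0.5,0.6,0.7 --out profile.tsv
```

(see `Rscript exec/hodgescore --help` for all subcommands).

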