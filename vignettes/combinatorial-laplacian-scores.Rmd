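---
title: "Combinatorial Laplacian scores: model, defaults and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial Laplacian scores: model, defaults and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodgescore)
```

## The model

A data set is a point cloud: samples with a pairwise dissimilarity
(`compute_distance_matrix()` offers Pearson correlation distance $1 - r$,
Euclidean, and cosine). A **Vietoris–Rips complex** at scale $\varepsilon$
represents its shape: vertices are samples, an edge joins $i, j$ whenever
$d(i,j) \le \varepsilon$, and triangles are exactly the 3-cliques of that
graph (the flag-complex definition — all higher structure is determined by
pairwise relations). Externally built complexes, e.g. Mapper nerves whose
nodes are clusters of samples, are ingested from explicit maximal-simplex
lists (`load_complex()`, `read_complex_json()`), with point-level features
averaged over node members (`aggregate_to_nodes()`).

A global vertex ordering orients every simplex. The signed incidence maps
$\partial_1$ (vertices × edges) and $\partial_2$ (edges × triangles) follow
the alternating-face convention; $\partial_1\partial_2 = 0$ holds exactly,
and the Hodge Laplacians are $L_0 = \partial_1 S \partial_1^\top$ (with
per-edge weights $S$, unit by default) and
$L_1 = \partial_1^\top \partial_1 + \partial_2 \partial_2^\top$. The kernel
of $L_q$ is the harmonic space, of dimension equal to the Betti number
$b_q$; `betti_numbers()` computes $b_0$ from connected components and
$b_1 = |E| - |V| + b_0 - \operatorname{rank}\partial_2$.

**Scores.** For a vertex feature $f$ with degree-weighted centering
$\tilde f$,
$$R(0) = \frac{\sum_e S_e (\tilde f_u - \tilde f_v)^2}{\tilde f^\top D_0 \tilde f},$$
identically the He–Cai–Niyogi Laplacian score of the 1-skeleton. For an
edge cochain $g$, $R(1) = g^\top L_1 g / g^\top g$; vertex features are
lifted to edges by endpoint averaging. The bivariate score replaces the
squared difference with a product of differences of two centered features
and normalizes by the geometric mean of their weighted variances, so that
the diagonal pair $(f, f)$ reproduces $R(0)$ and negative values indicate
high values in adjacent, non-overlapping regions.

## Numerical and design choices

* **$\varepsilon$ is a direct edge threshold** ($d \le \varepsilon$,
  boundary inclusive). The alternative "ball radius" convention differs by
  a factor of two ($d \le 2\varepsilon$); users porting scales from other
  tools should check which convention those use.
* **Orientation.** $R(0)$ is ordering-invariant. The mean lift feeding
  $R(1)$ is not: the signs of $\partial_1, \partial_2$ depend on the
  vertex ordering. The package default is the input sample order;
  `orient_by_root()` orders vertices by graph or metric distance from a
  chosen root (ties and unreachable vertices by original index), the
  recommended practice for trajectory-like data. $R(1)$ is exactly
  invariant under reorienting any edge when the cochain entry flips sign
  with it.
* **$R(1)$ normalization.** No centering, denominator $g^\top g$: the
  score is zero iff $g$ is harmonic, which is the semantically "trivial"
  direction at dimension 1 (constants are generically not in
  $\ker L_1$). The lift and normalization are isolated behind
  `lift_to_edges()` / `score_q1()` so alternatives can be swapped without
  touching callers.
* **Degenerate inputs.** Constant features (zero degree-weighted
  variance), zero cochains, and complexes with no edges yield `NA` scores
  with $p = 1$ — pipelines never crash on housekeeping-like features.
  A numerically tiny relative tolerance ($10^{-12}$) decides "zero
  variance"; score ties in permutation counting use a $10^{-9}$ relative
  tolerance so that exact symmetries (e.g. complete graphs, where the
  score is permutation-invariant) give $p = 1$ exactly.
* **Weights.** Unit edge weights by default, matching a binary VR
  skeleton; user-supplied weights (e.g. heat-kernel $e^{-d^2/t}$, or
  Mapper cluster-overlap sizes) enter $D_0$, $L_0$ and the 0-dimensional
  scores. $L_1$ is unweighted.
* **Permutation inference.** Vertex values are permuted (before lifting,
  for $q = 1$): permuting edge values directly would break the
  cochain/lift consistency. One shared, seed-derived permutation set is
  used for all features — cheaper and comparable across features. The
  add-one estimator $p = (1 + \#\{R_{perm} \le R_{obs}\})/(1 + B)$ is
  one-sided (low tail; for the bivariate score "low" includes negative
  values) and never returns 0.
* **Scale selection.** `select_epsilon()` counts BH rejections at the
  chosen FDR on each grid scale and returns the smallest maximizer
  (preferring sparser complexes). P-values are re-estimated at every
  scale from the same seed.

## The synthetic generators

The generators define the study conditions under which the package's
claims are tested; they are deliberately minimal.

* `simulate_two_populations()`: negative-binomial counts (dispersion 0.3,
  log-normal gene means with `meanlog = 1, sdlog = 1`), two equal
  populations, exactly `round(de_frac * n_genes)` DE genes whose means are
  multiplied by $2^{\mathrm{log2\_fc}}$ (default 2, i.e. 4-fold — the
  effect-size distribution of real comparative studies is data-derived and
  not modeled) in population 2. It emulates a two-population single-cell
  experiment; it does **not** model dropout, batch effects, library-size
  gradients or doublets, so passing benchmarks here bound what can be
  claimed about real data.
* `simulate_circle()`: equally spaced angles on a circle with isotropic
  Gaussian jitter — the minimal point cloud whose VR complex has
  $b_1 = 1$ at the right scale. It carries a constant `loop_feature`
  (value 1 everywhere) and a contiguous-arc indicator.
* `simulate_layers()`: horizontal bands of cells with in-band jitter and
  per-layer indicator features, emulating annotated populations in
  consecutive tissue layers for the bivariate score.

The expression pipeline normalizes counts per cell and log-transforms
(`normalize_log_counts()`): correlation distances on raw log counts mostly
measure library size.

Typical analysis sizes used in the package's own end-to-end checks: 100
cells × 1000 genes with 499 permutations for scale selection; 999
permutations for the circle tests; 199 permutations × 1000 features for
calibration. The permutation default for final analyses is 5000.

## Known limitations

* **Double use of the data.** When the complex is built from the same
  features that are scored (as is common in practice), the permutation
  null is anti-conservative: a feature helped shape the metric it is
  tested against. Empirically, scoring 300 null genes on a complex built
  from those same genes rejects ~6–8× the nominal rate at
  $\alpha = 0.05$, while features held out from complex construction are
  calibrated. When calibrated error control matters, build the complex
  from a feature split or an independent modality.
* **Significance at $q = 1$ is not loop-specificity.** On a
  topologically *homogeneous* complex (e.g. a uniform circle, where every
  vertex looks alike), the $R(1)$ permutation test can reject for any
  feature with coherent contiguous structure, not only for features
  spread around a non-contractible cycle; conversely a constant feature
  is invariant under permutation and always has $p = 1$ at any dimension.
  Loop-specific discrimination relies on contrast between triangle-rich
  (contractible) and cycle-like regions of the complex, which real
  heterogeneous data provide but minimal fixtures may not.
* **Cost of $R(1)$.** $L_1$ is an edges × edges operator; dense
  complexes make it large. The usual remedy is subsampling (the CLI's
  `--subsample`) and scoring at dimension 1 only on moderately sized
  complexes.
* Only dimensions $q \le 1$ (and triangles for $L_1$'s curl term) are
  implemented; no persistent homology, no exact Čech complexes, no
  analytic null distributions.
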