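# Synthetic generators reproducing the statistical and topological
# structure the scoring framework is designed for: two-population
# single-cell counts, noisy circular point clouds, and layered spatial
# point sets.  All generators take explicit seeds and never touch global
# random state.

#' Simulate two cell populations with a known fraction of DE genes
#'
#' Negative-binomial counts for two equally sized cell populations.  Gene
#' base means are drawn log-normally; a fixed fraction of genes is flagged
#' as differentially expressed and has its mean multiplied by
#' `2^log2_fc` in population 2.
#'
#' @param n_cells Even number of cells (split 50/50 across populations).
#' @param n_genes Number of genes.
#' @param de_frac Fraction of genes differentially expressed, in `[0, 1]`;
#'   exactly `round(de_frac * n_genes)` genes are flagged.
#' @param log2_fc Log2 fold change of DE genes in population 2.
#' @param dispersion Negative-binomial dispersion (the NB size parameter is
#'   `1 / dispersion`).
#' @param seed Integer seed.
#'
#' @return List with `counts` (gene-by-cell integer matrix) and `truth`, a
#'   list with `de_flags` (named logical per gene), `population_labels`
#'   (named integer 1/2 per cell) and `seed`.
#' @export
simulate_two_populations <- function(n_cells = 100L, n_genes = 1000L,
                                     de_frac = 0.1, log2_fc = 2,
                                     dispersion = 0.3, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  if (n_cells %% 2L != 0L) stopf("'n_cells' must be even (50/50 split)")
  if (!is.numeric(de_frac) || length(de_frac) != 1L || is.na(de_frac) ||
      de_frac < 0 || de_frac > 1) {
    stopf("'de_frac' must lie in [0, 1]")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stopf("'dispersion' must be positive")
  }
  n_de <- as.integer(round(de_frac * n_genes))
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  pop <- rep(c(1L, 2L), each = n_cells / 2L)
  names(pop) <- cell_ids

  with_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1)
    de_flags <- rep(FALSE, n_genes)
    de_flags[sample.int(n_genes, n_de)] <- TRUE
    mu <- matrix(base_mean, n_genes, n_cells)
    mu[de_flags, pop == 2L] <- mu[de_flags, pop == 2L] * 2^log2_fc
    counts <- matrix(
      stats::rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
      n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
    names(de_flags) <- gene_ids
    list(counts = counts,
         truth = list(de_flags = de_flags, population_labels = pop,
                      seed = seed))
  })
}

#' Simulate a noisy circular point cloud with loop and arc features
#'
#' Points are placed at equally spaced angles on a circle of the given
#' radius and jittered with isotropic Gaussian noise.  Two point features
#' accompany the coordinates: `loop_feature` takes the value 1 at every
#' point (high along the whole cycle) and `arc_feature` is the indicator of
#' a contiguous arc covering `arc_fraction` of the angles.
#'
#' @param n_points Number of points (>= 20).
#' @param radius Circle radius.
#' @param noise_sd Standard deviation of the Gaussian coordinate jitter.
#' @param arc_fraction Fraction of the circle covered by the arc, in (0, 1);
#'   the arc support has exactly `round(arc_fraction * n_points)` points.
#' @param seed Integer seed.
#'
#' @return List with `coords` (n x 2 matrix, point ids as rownames),
#'   `loop_feature`, `arc_feature` (named numeric vectors) and `seed`.
#' @export
simulate_circle <- function(n_points = 100L, radius = 1, noise_sd = 0.05,
                            arc_fraction = 0.25, seed = 1L) {
  n_points <- check_count(n_points, "n_points", min = 20L)
  if (!is.numeric(radius) || radius <= 0) stopf("'radius' must be positive")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stopf("'noise_sd' must be nonnegative")
  }
  if (!is.numeric(arc_fraction) || length(arc_fraction) != 1L ||
      is.na(arc_fraction) || arc_fraction <= 0 || arc_fraction >= 1) {
    stopf("'arc_fraction' must lie strictly between 0 and 1")
  }
  ids <- sprintf("p_%03d", seq_len(n_points))
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  coords <- with_seed(seed, {
    cbind(x = radius * cos(theta) + stats::rnorm(n_points, sd = noise_sd),
          y = radius * sin(theta) + stats::rnorm(n_points, sd = noise_sd))
  })
  rownames(coords) <- ids
  loop_feature <- stats::setNames(rep(1, n_points), ids)
  arc_feature <- stats::setNames(rep(0, n_points), ids)
  arc_feature[seq_len(round(arc_fraction * n_points))] <- 1
  list(coords = coords, loop_feature = loop_feature,
       arc_feature = arc_feature, seed = seed)
}

#' Simulate a layered spatial point set with per-layer indicators
#'
#' Cells occupy `n_layers` horizontal bands: layer `k` (0-based) occupies
#' the band `[k * layer_height, (k + 1) * layer_height)` in `y`, with cell
#' `y`-positions centered in the band plus Gaussian jitter (clamped inside
#' the band so the bands partition the plane), and `x` uniform over a
#' square region.  One binary indicator feature per layer partitions the
#' cells, emulating annotated cell populations in consecutive tissue
#' layers.
#'
#' @param n_layers Number of layers (>= 3).
#' @param cells_per_layer Cells per layer.
#' @param layer_height Band height `h`.
#' @param jitter_sd Gaussian jitter of `y` around each band center
#'   (defaults to `layer_height / 4`).
#' @param seed Integer seed.
#'
#' @return List with `coords` (n x 2 matrix), `indicators` (layer-by-cell
#'   0/1 matrix whose rows sum to the all-ones vector), `layer_labels`
#'   (integer per cell, 1-based) and `seed`.
#' @export
simulate_layers <- function(n_layers = 4L, cells_per_layer = 50L,
                            layer_height = 1, jitter_sd = layer_height / 4,
                            seed = 1L) {
  n_layers <- check_count(n_layers, "n_layers", min = 3L)
  cells_per_layer <- check_count(cells_per_layer, "cells_per_layer", min = 1L)
  if (!is.numeric(layer_height) || layer_height <= 0) {
    stopf("'layer_height' must be positive")
  }
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    stopf("'jitter_sd' must be nonnegative")
  }
  n <- n_layers * cells_per_layer
  h <- layer_height
  ids <- sprintf("c_%03d", seq_len(n))
  layer <- rep(seq_len(n_layers), each = cells_per_layer)
  pad <- 1e-6 * h
  coords <- with_seed(seed, {
    x <- stats::runif(n, 0, n_layers * h)
    y0 <- (layer - 0.5) * h + stats::rnorm(n, sd = jitter_sd)
    y <- pmin(pmax(y0, (layer - 1) * h + pad), layer * h - pad)
    cbind(x = x, y = y)
  })
  rownames(coords) <- ids
  indicators <- matrix(0, n_layers, n,
                       dimnames = list(sprintf("layer_%d", seq_len(n_layers)),
                                       ids))
  indicators[cbind(layer, seq_len(n))] <- 1
  list(coords = coords, indicators = indicators,
       layer_labels = stats::setNames(layer, ids), seed = seed)
}
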