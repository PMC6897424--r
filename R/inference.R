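# Permutation significance, BH-FDR control and scale selection.

#' Configuration for permutation inference
#'
#' @param n_perm Number of label permutations (>= 1; 5000 is the
#'   conventional choice for final analyses, smaller values are adequate
#'   for exploration).
#' @param seed Integer seed controlling the shared permutation set.
#' @param fdr_alpha FDR level for rejection counting, in (0, 1).
#' @param eps_grid Optional ascending vector of candidate scales for
#'   [select_epsilon()].
#'
#' @return An `inference_config` list.
#' @export
inference_config <- function(n_perm = 5000L, seed = 1L, fdr_alpha = 0.05,
                             eps_grid = NULL) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.numeric(fdr_alpha) || length(fdr_alpha) != 1L || is.na(fdr_alpha) ||
      fdr_alpha <= 0 || fdr_alpha >= 1) {
    stopf("'fdr_alpha' must be in (0, 1)")
  }
  if (!is.null(eps_grid)) {
    if (length(eps_grid) == 0L || any(!is.finite(eps_grid)) ||
        is.unsorted(eps_grid, strictly = FALSE)) {
      stopf("'eps_grid' must be a nonempty ascending numeric vector")
    }
    eps_grid <- as.numeric(eps_grid)
  }
  structure(list(n_perm = n_perm, seed = seed, fdr_alpha = fdr_alpha,
                 eps_grid = eps_grid),
            class = "inference_config")
}

# Shared permutation set: an n x n_perm matrix of vertex permutations,
# reproducible from the seed.  The same set is used for every feature so
# that p-values are comparable across features.
make_permutations <- function(n, n_perm, seed) {
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
}

# One-sided low-tail add-one estimator; ties (within a relative tolerance
# absorbing floating-point reordering of sums) count toward the null.
perm_pvalue_from_scores <- function(obs, perm_scores) {
  if (is.na(obs)) return(1)
  tol <- TIE_TOL * (abs(obs) + 1)
  (1 + sum(perm_scores <= obs + tol, na.rm = TRUE)) /
    (1 + length(perm_scores))
}

align_features <- function(features, complex) {
  features <- as_feature_matrix(features)
  n <- length(complex$vertices)
  if (ncol(features) != n) {
    stopf("features have %d samples but the complex has %d vertices",
          ncol(features), n)
  }
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), complex$vertices)) {
    idx <- match(complex$vertices, colnames(features))
    if (anyNA(idx)) {
      stopf("feature sample ids do not match the complex vertices")
    }
    features <- features[, idx, drop = FALSE]
  }
  features
}

# Observed scores for all features (rows) on a complex; q = 0 or 1.
# For q = 1 each vertex feature is lifted to an edge cochain first.
observed_scores <- function(F, ops, complex, q) {
  if (q == 0L) {
    score_q0_batch(F, ops)$score
  } else {
    if (ops$n_edges == 0L) return(rep(NA_real_, ncol(F)))
    e <- complex$edges
    G <- (F[e[, 1L], , drop = FALSE] + F[e[, 2L], , drop = FALSE]) / 2
    score_q1_batch(G, ops)$score
  }
}

#' Permutation p-value for a single feature
#'
#' Builds a null distribution for the combinatorial Laplacian score of one
#' feature by randomly permuting its vertex values (for `q = 1` the
#' permutation acts on vertex values before lifting to edges) and applies
#' the one-sided add-one estimator
#' `p = (1 + #\{permuted score <= observed\}) / (1 + n_perm)`: low scores
#' are significant and p-values never reach zero.  An undefined observed
#' score yields `p = 1`.
#'
#' @param f Numeric vertex feature in complex order.
#' @param complex A `simplicial_complex`.
#' @param q Score dimension, `0` or `1`.
#' @param config An [inference_config()].
#' @param edge_weights Optional per-edge weights (0-dimensional score only).
#'
#' @return List with elements `score` (observed) and `p_value`.
#' @export
permutation_pvalue <- function(f, complex, q = 0L, config = inference_config(),
                               edge_weights = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"),
            inherits(config, "inference_config"))
  if (!q %in% c(0L, 1L)) stopf("'q' must be 0 or 1")
  f <- as.numeric(f)
  n <- length(complex$vertices)
  if (length(f) != n) stopf("feature length %d does not match %d vertices",
                            length(f), n)
  ops <- boundary_matrices(complex, edge_weights = edge_weights)
  obs <- suppressWarnings(observed_scores(matrix(f, ncol = 1L), ops, complex, q))
  perms <- make_permutations(n, config$n_perm, config$seed)
  Fp <- matrix(f[perms], nrow = n)              # one column per permutation
  perm_scores <- observed_scores(Fp, ops, complex, q)
  list(score = as.numeric(obs),
       p_value = perm_pvalue_from_scores(obs, perm_scores))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment with monotonicity enforcement, as in
#' `stats::p.adjust(method = "BH")`, after validating that all p-values lie
#' in (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stopf("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Score and test all features on a complex
#'
#' Computes the `q`-dimensional combinatorial Laplacian score of every
#' feature, a permutation p-value per feature from a shared seed-derived
#' permutation set (the same vertex permutations for every feature, so
#' p-values are comparable across features), and BH q-values across all
#' tested features.  Features with undefined scores (e.g. constant
#' features) propagate as `NA` score with `p = q = 1`.
#'
#' @param complex A `simplicial_complex`.
#' @param features Feature-by-sample numeric matrix; colnames, if present,
#'   must match the complex's vertex ids (any order).
#' @param q Score dimension, `0` or `1`.
#' @param config An [inference_config()].
#' @param edge_weights Optional per-edge weights (0-dimensional score only).
#'
#' @return A data frame with columns `feature_id`, `q`, `score`, `p_value`,
#'   `q_value`, sorted by ascending score (undefined scores last).
#' @export
score_table <- function(complex, features, q = 0L,
                        config = inference_config(), edge_weights = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"),
            inherits(config, "inference_config"))
  if (!q %in% c(0L, 1L)) stopf("'q' must be 0 or 1")
  features <- align_features(features, complex)
  n <- length(complex$vertices)
  F <- t(features)                                   # vertices x features
  ops <- boundary_matrices(complex, edge_weights = edge_weights)

  obs <- observed_scores(F, ops, complex, q)
  counts <- integer(ncol(F))
  perms <- make_permutations(n, config$n_perm, config$seed)
  tol <- TIE_TOL * (abs(obs) + 1)
  for (b in seq_len(config$n_perm)) {
    sb <- observed_scores(F[perms[, b], , drop = FALSE], ops, complex, q)
    counts <- counts + as.integer(!is.na(sb) & !is.na(obs) & sb <= obs + tol)
  }
  p <- ifelse(is.na(obs), 1, (1 + counts) / (1 + config$n_perm))
  out <- data.frame(feature_id = rownames(features),
                    q = q,
                    score = obs,
                    p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out[order(out$score, seq_len(nrow(out)), na.last = TRUE), , drop = FALSE]
}

#' Score and test all feature pairs on a complex
#'
#' Computes the bivariate 0-dimensional combinatorial Laplacian score of
#' every unordered feature pair, with a permutation null built by jointly
#' permuting the vertex labels of the second feature of each pair while the
#' first stays fixed.  Low scores (including negative ones, indicating
#' adjacent non-overlapping high-value regions) are significant; BH
#' adjustment is applied across all pairs.
#'
#' @inheritParams score_table
#' @return A data frame with columns `feature_id_r`, `feature_id_s`, `q`,
#'   `score`, `p_value`, `q_value`, sorted by ascending score.
#' @export
pair_score_table <- function(complex, features, config = inference_config(),
                             edge_weights = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"),
            inherits(config, "inference_config"))
  features <- align_features(features, complex)
  m <- nrow(features)
  if (m < 2L) stopf("at least 2 features are required to score pairs")
  n <- length(complex$vertices)
  F <- t(features)
  ops <- boundary_matrices(complex, edge_weights = edge_weights)

  base <- score_q0_batch(F, ops)
  cross <- function(A, B) as.matrix(Matrix::crossprod(A, ops$L0 %*% B))
  num <- cross(F, F)
  den_ok <- base$den > 0
  scale <- sqrt(base$den)
  obs_mat <- num / outer(scale, scale)
  obs_mat[!den_ok, ] <- NA_real_
  obs_mat[, !den_ok] <- NA_real_

  pairs <- utils::combn(m, 2L)
  obs <- obs_mat[cbind(pairs[1L, ], pairs[2L, ])]

  counts <- integer(ncol(pairs))
  perms <- make_permutations(n, config$n_perm, config$seed)
  tol <- TIE_TOL * (abs(obs) + 1)
  for (b in seq_len(config$n_perm)) {
    Fp <- F[perms[, b], , drop = FALSE]
    bp <- score_q0_batch(Fp, ops)
    nump <- cross(F, Fp)                 # rows fixed, columns permuted
    sp_mat <- nump / outer(scale, sqrt(bp$den))
    sp <- sp_mat[cbind(pairs[1L, ], pairs[2L, ])]
    counts <- counts + as.integer(!is.na(sp) & !is.na(obs) & sp <= obs + tol)
  }
  p <- ifelse(is.na(obs), 1, (1 + counts) / (1 + config$n_perm))
  out <- data.frame(feature_id_r = rownames(features)[pairs[1L, ]],
                    feature_id_s = rownames(features)[pairs[2L, ]],
                    q = 0L,
                    score = obs,
                    p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out[order(out$score, seq_len(nrow(out)), na.last = TRUE), , drop = FALSE]
}

#' Select the complex scale by maximizing rejections at fixed FDR
#'
#' For each candidate scale in `config$eps_grid`, builds the Vietoris-Rips
#' complex, scores and tests all features ([score_table()]) and counts BH
#' rejections at `config$fdr_alpha`.  Returns the scale with the most
#' rejections (ties resolved toward the smallest scale, preferring sparser
#' complexes) together with the full rejection profile.  P-values are
#' re-estimated independently at every scale.
#'
#' @param dist Square symmetric distance matrix.
#' @param features Feature-by-sample numeric matrix.
#' @param q Score dimension, `0` or `1`.
#' @param config An [inference_config()] with a nonempty `eps_grid`.
#'
#' @return List with `best_epsilon`, `n_rejected` (at the best scale) and
#'   `profile`, a data frame with columns `epsilon`, `n_edges`,
#'   `n_triangles`, `n_rejected`.
#' @export
select_epsilon <- function(dist, features, q = 0L,
                           config = inference_config()) {
  stopifnot(inherits(config, "inference_config"))
  if (is.null(config$eps_grid)) stopf("'config$eps_grid' must be supplied")
  d <- validate_distance_matrix(dist)
  grid <- config$eps_grid
  profile <- data.frame(epsilon = grid, n_edges = NA_integer_,
                        n_triangles = NA_integer_, n_rejected = NA_integer_)
  for (i in seq_along(grid)) {
    cx <- build_vietoris_rips(d, grid[i], max_dim = if (q == 0L) 1L else 2L)
    sz <- complex_size(cx)
    tab <- score_table(cx, features, q = q, config = config)
    profile$n_edges[i] <- sz[["n_edges"]]
    profile$n_triangles[i] <- sz[["n_triangles"]]
    profile$n_rejected[i] <- sum(tab$q_value <= config$fdr_alpha &
                                   !is.na(tab$score))
  }
  best <- which.max(profile$n_rejected)    # first maximum = smallest epsilon
  list(best_epsilon = grid[best],
       n_rejected = profile$n_rejected[best],
       profile = profile)
}

#' Rank-based AUC for recovering known positives
#'
#' Area under the receiver-operating characteristic curve for a score in
#' which *lower* values indicate positives (scores are rank-inverted before
#' the standard midrank computation).  Undefined scores are treated as
#' least-positive.
#'
#' @param scores Numeric scores, lower = more likely positive.
#' @param truth_labels Logical (or 0/1) vector of true positives.
#'
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth_labels) {
  truth <- as.logical(truth_labels)
  if (length(scores) != length(truth) || anyNA(truth)) {
    stopf("'scores' and 'truth_labels' must be aligned logical/numeric vectors")
  }
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stopf("'truth_labels' must contain both classes")
  x <- -as.numeric(scores)                 # higher = more positive
  x[is.na(x)] <- -Inf
  r <- rank(x)                             # midranks for ties
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
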