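# Combinatorial Laplacian scores for vertex features and edge cochains.
#
# Internal *_batch engines score many features at once (columns of a
# vertex-by-feature matrix); the exported single-feature functions and the
# permutation machinery in inference.R are thin wrappers around them.

DEN_TOL <- 1e-12   # relative tolerance below which a weighted variance is zero
TIE_TOL <- 1e-9    # relative tolerance when comparing permuted to observed

# F: n_vertices x m matrix. Returns list(score, num, den); score is NA where
# the degree-weighted variance vanishes (constant features, or no edges).
score_q0_batch <- function(F, ops) {
  m <- ncol(F)
  if (ops$n_edges == 0L || sum(ops$D0) == 0) {
    return(list(score = rep(NA_real_, m), num = rep(NA_real_, m),
                den = rep(0, m)))
  }
  D <- ops$D0
  sD <- sum(D)
  num <- colSums(F * as.matrix(ops$L0 %*% F))      # f'L0f; centering drops out
  wmean <- as.numeric(crossprod(D, F)) / sD
  msq <- as.numeric(crossprod(D, F^2))
  den <- msq - sD * wmean^2                        # f~' D0 f~
  undef <- den <= DEN_TOL * pmax(msq, 1)
  score <- ifelse(undef, NA_real_, pmax(num, 0) / den)
  list(score = score, num = num, den = ifelse(undef, 0, den))
}

# G: n_edges x m matrix of edge cochains.
score_q1_batch <- function(G, ops) {
  m <- ncol(G)
  if (ops$n_edges == 0L) {
    return(list(score = rep(NA_real_, m)))
  }
  den <- colSums(G^2)
  num <- colSums(G * as.matrix(ops$L1 %*% G))
  undef <- den <= DEN_TOL * pmax(colSums(abs(G))^2, 1)
  list(score = ifelse(undef, NA_real_, pmax(num, 0) / den))
}

#' 0-dimensional combinatorial Laplacian score of a vertex feature
#'
#' The ordinary (He-Cai-Niyogi) Laplacian score of the complex's graph
#' skeleton: with `f~` the degree-weighted centering of `f`, the score is
#' `sum_e S_e (f~_u - f~_v)^2 / (f~' D0 f~)`.  Low scores indicate features
#' whose high values concentrate on densely connected regions of the
#' complex.
#'
#' @param f Numeric vertex feature, one value per vertex in complex order.
#' @param ops `boundary_operators` from [boundary_matrices()].
#'
#' @return A single nonnegative number, or `NA` (with a warning) for
#'   degenerate features whose degree-weighted variance is zero (constant
#'   features, or complexes with no edges).
#' @export
score_q0 <- function(f, ops) {
  stopifnot(inherits(ops, "boundary_operators"))
  f <- as.numeric(f)
  if (length(f) != ops$n_vertices) {
    stopf("feature length %d does not match %d vertices",
          length(f), ops$n_vertices)
  }
  s <- score_q0_batch(matrix(f, ncol = 1L), ops)$score
  if (is.na(s)) {
    warnf("feature has zero degree-weighted variance; score is undefined")
  }
  s
}

#' Lift a vertex feature to an edge cochain
#'
#' Evaluates a vertex feature on the oriented edges of a complex.  With
#' `method = "mean"`, edge `(u, v)` (with `rank(u) < rank(v)`) receives
#' `(f_u + f_v) / 2`.  The result is deterministic given the complex's
#' vertex ordering; use [orient_by_root()] to control that ordering.
#'
#' @inheritParams score_q0
#' @param complex A `simplicial_complex`.
#' @param method Lift rule; only `"mean"` is implemented.
#'
#' @return Numeric edge cochain in canonical edge order (length 0 when the
#'   complex has no edges).
#' @export
lift_to_edges <- function(f, complex, method = c("mean")) {
  stopifnot(inherits(complex, "simplicial_complex"))
  method <- match.arg(method)
  f <- as.numeric(f)
  if (length(f) != length(complex$vertices)) {
    stopf("feature length %d does not match %d vertices",
          length(f), length(complex$vertices))
  }
  if (nrow(complex$edges) == 0L) return(numeric(0))
  (f[complex$edges[, 1L]] + f[complex$edges[, 2L]]) / 2
}

#' 1-dimensional combinatorial Laplacian score of an edge cochain
#'
#' The Rayleigh quotient `g' L1 g / g' g` of the edge Laplacian.  The score
#' is zero exactly when `g` is a harmonic 1-cochain, i.e. aligned with a
#' non-contractible cycle of the complex; low scores indicate cochains
#' concentrated along such loops, while cochains supported on contractible
#' or triangle-filled regions score higher.
#'
#' @param g Numeric edge cochain in canonical edge order (e.g. from
#'   [lift_to_edges()]).
#' @param ops `boundary_operators` from [boundary_matrices()].
#'
#' @return A single nonnegative number, or `NA` (with a warning) for the
#'   zero cochain.
#' @export
score_q1 <- function(g, ops) {
  stopifnot(inherits(ops, "boundary_operators"))
  g <- as.numeric(g)
  if (length(g) != ops$n_edges) {
    stopf("cochain length %d does not match %d edges", length(g), ops$n_edges)
  }
  if (ops$n_edges == 0L) {
    warnf("complex has no edges; 1-dimensional score is undefined")
    return(NA_real_)
  }
  s <- score_q1_batch(matrix(g, ncol = 1L), ops)$score
  if (is.na(s)) warnf("zero cochain; score is undefined")
  s
}

#' Bivariate 0-dimensional combinatorial Laplacian score
#'
#' Cross-feature analogue of [score_q0()], in analogy to covariance:
#' `sum_e S_e (f~_u - f~_v)(g~_u - g~_v) / sqrt((f~' D0 f~)(g~' D0 g~))`
#' with both features degree-centered.  The score is symmetric in its
#' arguments and reduces to `score_q0(f)` when `g = f`.  Low (in particular
#' negative) values indicate pairs of features taking high values in
#' non-overlapping but adjacent regions of the complex.
#'
#' @param f,g Numeric vertex features in complex order.
#' @param ops `boundary_operators` from [boundary_matrices()].
#'
#' @return A single signed number, or `NA` (with a warning) when either
#'   feature has zero degree-weighted variance.
#' @export
score_bivariate_q0 <- function(f, g, ops) {
  stopifnot(inherits(ops, "boundary_operators"))
  f <- as.numeric(f); g <- as.numeric(g)
  if (length(f) != ops$n_vertices || length(g) != ops$n_vertices) {
    stopf("feature lengths must match %d vertices", ops$n_vertices)
  }
  bf <- score_q0_batch(matrix(f, ncol = 1L), ops)
  bg <- score_q0_batch(matrix(g, ncol = 1L), ops)
  if (is.na(bf$score) || is.na(bg$score)) {
    warnf("a feature has zero degree-weighted variance; score is undefined")
    return(NA_real_)
  }
  # cross numerator via polarization of the L0 quadratic form (L0 1 = 0, so
  # the degree-weighted centering drops out of the numerator)
  num <- as.numeric(crossprod(f, as.matrix(ops$L0 %*% g)))
  num / sqrt(bf$den * bg$den)
}

#' Aggregate per-sample values to the nodes of a cluster complex
#'
#' Mapper-style complexes have nodes that are clusters of samples; a
#' point-level feature is evaluated on such a complex by averaging it over
#' the member samples of each node.
#'
#' @param point_feature Named numeric vector of per-sample values, or a
#'   feature-by-sample matrix with sample ids as colnames.
#' @param membership Named list mapping each node id to a nonempty vector
#'   of member sample ids.
#' @param method Aggregation rule; only `"mean"` is implemented.
#'
#' @return A numeric vector (or feature-by-node matrix) of node values in
#'   the order of `membership`.
#' @export
aggregate_to_nodes <- function(point_feature, membership, method = c("mean")) {
  method <- match.arg(method)
  if (!is.list(membership) || is.null(names(membership)) ||
      any(!nzchar(names(membership)))) {
    stopf("'membership' must be a named list of node member sample ids")
  }
  mat <- if (is.matrix(point_feature)) point_feature else
    matrix(point_feature, nrow = 1L,
           dimnames = list("feature_1", names(point_feature)))
  if (is.null(colnames(mat))) stopf("'point_feature' must carry sample ids")
  out <- matrix(NA_real_, nrow(mat), length(membership),
                dimnames = list(rownames(mat), names(membership)))
  for (k in seq_along(membership)) {
    node <- names(membership)[k]
    members <- as.character(membership[[k]])
    if (length(members) == 0L) stopf("node '%s' has no member samples", node)
    idx <- match(members, colnames(mat))
    if (anyNA(idx)) {
      stopf("node '%s' references unknown sample '%s'",
            node, members[which(is.na(idx))[1L]])
    }
    out[, k] <- rowMeans(mat[, idx, drop = FALSE])
  }
  if (!is.matrix(point_feature)) {
    stats::setNames(out[1L, ], colnames(out))
  } else {
    out
  }
}

#' Filter features by detection fraction
#'
#' Retains features detected (value strictly greater than zero) in a
#' fraction of samples strictly between `min_frac` and `max_frac`.  This is
#' the usual pre-filter before scoring single-cell expression: ubiquitous
#' and near-silent genes carry little localization signal.
#'
#' @param expr Feature-by-sample numeric matrix.
#' @param min_frac,max_frac Detection-fraction bounds with
#'   `0 <= min_frac < max_frac <= 1`.
#'
#' @return Character vector of retained feature ids.
#' @export
feature_filter <- function(expr, min_frac = 0.01, max_frac = 0.25) {
  expr <- as_feature_matrix(expr)
  if (!is.numeric(min_frac) || !is.numeric(max_frac) ||
      length(min_frac) != 1L || length(max_frac) != 1L ||
      is.na(min_frac) || is.na(max_frac) ||
      min_frac < 0 || max_frac > 1 || min_frac >= max_frac) {
    stopf("bounds must satisfy 0 <= min_frac < max_frac <= 1")
  }
  frac <- rowMeans(expr > 0)
  rownames(expr)[frac > min_frac & frac < max_frac]
}

#' Observed scores for all features, without significance testing
#'
#' Convenience wrapper computing the `q`-dimensional combinatorial
#' Laplacian score of every feature (rows) on a complex, with no
#' permutation testing.  Useful for pure rankings, e.g. AUC benchmarks
#' against known positives.
#'
#' @param complex A `simplicial_complex`.
#' @param features Feature-by-sample numeric matrix; colnames, if present,
#'   must match the complex's vertex ids.
#' @param q Score dimension, `0` or `1` (vertex features are lifted with
#'   [lift_to_edges()] for `q = 1`).
#' @param edge_weights Optional per-edge weights (0-dimensional score only).
#'
#' @return Named numeric vector of scores (`NA` for degenerate features).
#' @export
score_features <- function(complex, features, q = 0L, edge_weights = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"))
  if (!q %in% c(0L, 1L)) stopf("'q' must be 0 or 1")
  features <- align_features(features, complex)
  ops <- boundary_matrices(complex, edge_weights = edge_weights)
  s <- observed_scores(t(features), ops, complex, q)
  stats::setNames(s, rownames(features))
}
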