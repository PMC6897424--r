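# Oriented simplicial complexes of dimension <= 2.
#
# A complex stores an ordered vertex vector (the global ordering that induces
# all simplex orientations), an edge matrix and a triangle matrix of vertex
# indices into that ordering.  Each simplex row is ascending in the ordering
# and rows are sorted lexicographically, so the edge/triangle order is
# canonical and reproducible.

new_simplicial_complex <- function(vertices, edges, triangles, epsilon = NULL) {
  structure(
    list(vertices = as.character(vertices),
         edges = edges,
         triangles = triangles,
         epsilon = epsilon),
    class = "simplicial_complex"
  )
}

empty_simplex_matrix <- function(k) {
  matrix(integer(0), ncol = k, nrow = 0L)
}

# Sort each row ascending, drop duplicate rows, order rows lexicographically.
canonicalize_simplices <- function(m, k) {
  if (is.null(m) || length(m) == 0L) return(empty_simplex_matrix(k))
  m <- matrix(as.integer(m), ncol = k)
  m <- t(apply(m, 1L, sort))
  if (k == 1L) m <- matrix(m, ncol = 1L)
  m <- unique(m)
  ord <- do.call(order, lapply(seq_len(k), function(j) m[, j]))
  m <- m[ord, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Number of vertices, edges and triangles of a complex
#'
#' @param complex A `simplicial_complex`.
#' @return Named integer vector with elements `n_vertices`, `n_edges`,
#'   `n_triangles`.
#' @export
complex_size <- function(complex) {
  stopifnot(inherits(complex, "simplicial_complex"))
  c(n_vertices = length(complex$vertices),
    n_edges = nrow(complex$edges),
    n_triangles = nrow(complex$triangles))
}

#' @export
print.simplicial_complex <- function(x, ...) {
  sz <- complex_size(x)
  cat(sprintf(
    "Simplicial complex: %d vertices, %d edges, %d triangles%s\n",
    sz[["n_vertices"]], sz[["n_edges"]], sz[["n_triangles"]],
    if (!is.null(x$epsilon)) sprintf(" (epsilon = %g)", x$epsilon) else ""
  ))
  invisible(x)
}

#' Vietoris-Rips complex of a distance matrix
#'
#' Builds the flag (clique) complex of the graph connecting samples at
#' distance at most `epsilon`: an edge `(i, j)` is present iff
#' `d(i, j) <= epsilon` (boundary inclusive), and the triangles are exactly
#' the 3-cliques of that edge set.  `epsilon` is the direct edge-distance
#' threshold, not a ball radius; see the package vignette for the
#' factor-of-two ambiguity between the two conventions.
#'
#' @param dist Square symmetric distance matrix (e.g. from
#'   [compute_distance_matrix()]).
#' @param epsilon Nonnegative scale threshold.
#' @param max_dim Maximum simplex dimension, `1` (graph only) or `2`.
#'
#' @return A `simplicial_complex` whose vertex ordering is the input sample
#'   order.  With `epsilon` below the smallest off-diagonal distance the
#'   complex has no edges; downstream scores then report undefined values
#'   rather than failing.
#' @export
build_vietoris_rips <- function(dist, epsilon, max_dim = 2L) {
  d <- validate_distance_matrix(dist)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0) {
    stopf("'epsilon' must be a single nonnegative number")
  }
  if (!max_dim %in% c(1L, 2L)) stopf("'max_dim' must be 1 or 2")
  n <- nrow(d)
  adj <- d <= epsilon
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  edges <- canonicalize_simplices(cbind(edges[, 1L], edges[, 2L]), 2L)

  triangles <- empty_simplex_matrix(3L)
  if (max_dim == 2L && nrow(edges) >= 3L) {
    g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
    tri <- igraph::triangles(g)
    if (length(tri)) {
      triangles <- canonicalize_simplices(
        matrix(as.integer(tri), ncol = 3L, byrow = TRUE), 3L)
    }
  }
  new_simplicial_complex(rownames(d), edges, triangles, epsilon = epsilon)
}

#' Build a complex from explicit maximal simplices
#'
#' Ingests an externally constructed simplicial complex (for example a
#' Mapper nerve) given as a list of maximal simplices over named vertices.
#' Faces are completed automatically so the result is face-closed.
#'
#' @param simplices List of character vectors, each a simplex of 1 to 3
#'   vertex ids (dimension 0 to 2).
#' @param vertex_ids Character vector of all vertex ids; its order is the
#'   orientation order of the complex.
#' @param epsilon Optional scale annotation carried along.
#'
#' @return A `simplicial_complex`.
#' @export
load_complex <- function(simplices, vertex_ids, epsilon = NULL) {
  vertex_ids <- as.character(vertex_ids)
  if (anyDuplicated(vertex_ids)) stopf("duplicate vertex id in 'vertex_ids'")
  if (!is.list(simplices)) stopf("'simplices' must be a list of vertex-id vectors")
  edges <- list()
  triangles <- list()
  for (s in simplices) {
    s <- as.character(unlist(s, use.names = FALSE))
    idx <- match(s, vertex_ids)
    if (anyNA(idx)) {
      stopf("simplex references unknown vertex '%s'", s[which(is.na(idx))[1L]])
    }
    if (anyDuplicated(idx)) stopf("simplex has repeated vertices")
    k <- length(idx)
    if (k > 3L) {
      stopf("simplex of dimension %d found; only dimensions 0-2 are supported",
            k - 1L)
    }
    if (k == 2L) edges[[length(edges) + 1L]] <- idx
    if (k == 3L) {
      triangles[[length(triangles) + 1L]] <- idx
      edges <- c(edges, list(idx[c(1L, 2L)], idx[c(1L, 3L)], idx[c(2L, 3L)]))
    }
  }
  new_simplicial_complex(
    vertex_ids,
    canonicalize_simplices(do.call(rbind, edges), 2L),
    canonicalize_simplices(do.call(rbind, triangles), 3L),
    epsilon = epsilon
  )
}

#' Reorder a complex's vertices by distance from a root
#'
#' Fixes the orientation of a complex by ordering vertices according to
#' ascending distance from a chosen root vertex, either graph distance on
#' the 1-skeleton (unweighted shortest path) or metric distance from a
#' supplied distance matrix.  Ties are broken by the original vertex index,
#' and vertices unreachable from the root are appended last in original
#' order.  Edges and triangles are re-canonicalized to the new ordering.
#' This mirrors the common practice of orienting a trajectory complex from
#' a terminally differentiated cell before computing 1-dimensional scores.
#'
#' @param complex A `simplicial_complex`.
#' @param root Vertex id (character) or index of the root.
#' @param mode `"graph_distance"` or `"metric_distance"`.
#' @param dist Distance matrix over the complex's vertices, required for
#'   `mode = "metric_distance"`; rows must align with the vertex order.
#'
#' @return The reordered `simplicial_complex`.
#' @export
orient_by_root <- function(complex, root,
                           mode = c("graph_distance", "metric_distance"),
                           dist = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"))
  mode <- match.arg(mode)
  n <- length(complex$vertices)
  if (is.character(root)) {
    ri <- match(root, complex$vertices)
    if (is.na(ri)) stopf("unknown root vertex '%s'", root)
  } else {
    ri <- as.integer(root)
    if (is.na(ri) || ri < 1L || ri > n) stopf("unknown root vertex index %s", root)
  }

  if (mode == "graph_distance") {
    g <- igraph::make_graph(t(complex$edges), n = n, directed = FALSE)
    dvec <- as.numeric(igraph::distances(g, v = ri))
  } else {
    if (is.null(dist)) stopf("'metric_distance' mode requires a distance matrix")
    d <- validate_distance_matrix(dist)
    if (nrow(d) != n) stopf("distance matrix size does not match the complex")
    dvec <- d[ri, ]
  }
  new_order <- order(dvec, seq_len(n))    # Inf (unreachable) sorts last
  rank_of_old <- integer(n)
  rank_of_old[new_order] <- seq_len(n)

  remap <- function(m, k) {
    if (nrow(m) == 0L) return(m)
    canonicalize_simplices(matrix(rank_of_old[m], ncol = k), k)
  }
  new_simplicial_complex(
    complex$vertices[new_order],
    remap(complex$edges, 2L),
    remap(complex$triangles, 3L),
    epsilon = complex$epsilon
  )
}

#' Betti numbers b0 and b1 of a complex
#'
#' `b0` is the number of connected components of the 1-skeleton and
#' `b1 = n_edges - n_vertices + b0 - rank(d2)`, the number of independent
#' non-contractible loops after triangle fill-in.
#'
#' @param complex A `simplicial_complex`.
#' @return Named numeric vector `c(b0 = , b1 = )`.
#' @export
betti_numbers <- function(complex) {
  stopifnot(inherits(complex, "simplicial_complex"))
  n <- length(complex$vertices)
  ne <- nrow(complex$edges)
  g <- igraph::make_graph(t(complex$edges), n = n, directed = FALSE)
  b0 <- igraph::components(g)$no
  rank_d2 <- 0L
  if (nrow(complex$triangles) > 0L) {
    ops <- boundary_matrices(complex)
    rank_d2 <- qr(as.matrix(ops$d2), tol = 1e-8)$rank
  }
  c(b0 = b0, b1 = ne - n + b0 - rank_d2)
}
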