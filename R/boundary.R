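# Signed boundary operators and combinatorial Hodge Laplacians.

#' Boundary operators and Laplacians of a complex
#'
#' Assembles the signed incidence maps `d1` (vertices x edges) and `d2`
#' (edges x triangles) of an oriented complex, together with the vertex
#' Laplacian `L0 = D0 - S` (as a vertex operator), the edge Laplacian
#' `L1 = t(d1) d1 + d2 t(d2)`, the per-vertex degree weights `D0` and the
#' per-edge weights `S`.  Orientation is induced by the complex's global
#' vertex ordering: the column of `d1` for edge `(u, v)` with
#' `rank(u) < rank(v)` is `-1` at `u` and `+1` at `v`; the column of `d2`
#' for triangle `(u, v, w)` ascending is `+1` on `(v, w)`, `-1` on
#' `(u, w)`, `+1` on `(u, v)`.  The chain-complex identity `d1 %*% d2 = 0`
#' holds exactly.
#'
#' @param complex A `simplicial_complex`.
#' @param edge_weights Optional nonnegative vector of per-edge weights `S`
#'   in the canonical edge order; defaults to unit weights.  Weights enter
#'   `D0`, `L0` and the 0-dimensional scores; `L1` is unweighted.
#'
#' @return An object of class `boundary_operators`: a list with sparse
#'   matrices `d1`, `d2`, `L0`, `L1`, the degree vector `D0`, the weight
#'   vector `S`, and the complex sizes.
#' @export
boundary_matrices <- function(complex, edge_weights = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"))
  n <- length(complex$vertices)
  edges <- complex$edges
  triangles <- complex$triangles
  ne <- nrow(edges)
  nt <- nrow(triangles)

  if (is.null(edge_weights)) {
    S <- rep(1, ne)
  } else {
    if (length(edge_weights) != ne) {
      stopf("'edge_weights' has length %d but the complex has %d edges",
            length(edge_weights), ne)
    }
    if (any(!is.finite(edge_weights)) || any(edge_weights < 0)) {
      stopf("'edge_weights' must be finite and nonnegative")
    }
    S <- as.numeric(edge_weights)
  }

  d1 <- Matrix::sparseMatrix(
    i = as.integer(t(edges)),
    j = rep(seq_len(ne), each = 2L),
    x = rep(c(-1, 1), times = ne),
    dims = c(n, max(ne, 0L))
  )

  if (nt > 0L) {
    edge_key <- paste(edges[, 1L], edges[, 2L])
    face <- function(a, b) match(paste(a, b), edge_key)
    d2 <- Matrix::sparseMatrix(
      i = c(face(triangles[, 2L], triangles[, 3L]),
            face(triangles[, 1L], triangles[, 3L]),
            face(triangles[, 1L], triangles[, 2L])),
      j = rep(seq_len(nt), times = 3L),
      x = rep(c(1, -1, 1), each = nt),
      dims = c(ne, nt)
    )
  } else {
    d2 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(ne, 0L))
  }

  D0 <- if (ne > 0L) as.numeric(abs(d1) %*% S) else numeric(n)

  L0 <- d1 %*% Matrix::Diagonal(x = S, n = max(ne, 0L)) %*% Matrix::t(d1)
  L1 <- Matrix::crossprod(d1) + Matrix::tcrossprod(d2)

  structure(
    list(d1 = d1, d2 = d2, L0 = L0, L1 = L1, D0 = D0, S = S,
         n_vertices = n, n_edges = ne, n_triangles = nt),
    class = "boundary_operators"
  )
}

#' @export
print.boundary_operators <- function(x, ...) {
  cat(sprintf(
    "Boundary operators: %d vertices, %d edges, %d triangles (nnz d1 = %d, nnz d2 = %d)\n",
    x$n_vertices, x$n_edges, x$n_triangles,
    Matrix::nnzero(x$d1), Matrix::nnzero(x$d2)
  ))
  invisible(x)
}
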