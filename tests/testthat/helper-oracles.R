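# Independent dense oracles and fixture builders.  These deliberately avoid
# the package's sparse code paths: brute-force enumeration for complexes,
# dense matrix algebra for scores and boundary maps, and a hand-coded
# step-up for BH.

# Dense He-Cai-Niyogi Laplacian score on a weighted graph given its full
# weight matrix W (zero diagonal, symmetric).
oracle_laplacian_score <- function(f, W) {
  D <- rowSums(W)
  one <- rep(1, length(f))
  ft <- f - as.numeric(crossprod(f, D) / sum(D)) * one
  num <- as.numeric(t(ft) %*% (diag(D) - W) %*% ft)
  den <- as.numeric(t(ft) %*% diag(D) %*% ft)
  num / den
}

# Brute-force Vietoris-Rips: test every pair and triple directly.
oracle_vr <- function(d, eps) {
  n <- nrow(d)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (d[i, j] <= eps) edges <- rbind(edges, c(i, j))
    }
  }
  triangles <- NULL
  if (n >= 3L) {
    for (trip in utils::combn(n, 3L, simplify = FALSE)) {
      i <- trip[1L]; j <- trip[2L]; k <- trip[3L]
      if (d[i, j] <= eps && d[i, k] <= eps && d[j, k] <= eps) {
        triangles <- rbind(triangles, c(i, j, k))
      }
    }
  }
  list(edges = if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
       triangles = if (is.null(triangles)) matrix(integer(0), 0, 3)
                   else triangles)
}

# Dense boundary matrices built with the textbook alternating-face formula,
# looping simplex by simplex (independent of the package's vectorized
# assembly).
oracle_boundaries <- function(complex) {
  n <- length(complex$vertices)
  ne <- nrow(complex$edges)
  nt <- nrow(complex$triangles)
  d1 <- matrix(0, n, ne)
  for (e in seq_len(ne)) {
    verts <- complex$edges[e, ]
    for (i in 1:2) d1[verts[-i], e] <- (-1)^(i - 1)  # delete face i, sign (-1)^(i-1)
  }
  d2 <- matrix(0, ne, nt)
  if (nt > 0L) {
    find_edge <- function(u, v) {
      which(complex$edges[, 1L] == u & complex$edges[, 2L] == v)
    }
    for (t in seq_len(nt)) {
      verts <- complex$triangles[t, ]
      for (i in 1:3) {
        face <- verts[-i]
        d2[find_edge(face[1L], face[2L]), t] <- (-1)^(i + 1)
      }
    }
  }
  list(d1 = d1, d2 = d2)
}

# Hand-coded BH step-up with monotonicity enforcement.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
}

# Random VR complex on n uniform 2-D points; eps drawn between distance
# quantiles so the complex is neither empty nor complete in most draws.
random_vr_complex <- function(n, seed, q_lo = 0.1, q_hi = 0.5) {
  set.seed(seed)
  pts <- matrix(runif(2L * n), ncol = 2L)
  rownames(pts) <- paste0("v", seq_len(n))
  d <- compute_distance_matrix(pts, "euclidean")
  off <- d[upper.tri(d)]
  eps <- stats::quantile(off, runif(1, q_lo, q_hi))
  list(dist = d, complex = build_vietoris_rips(d, eps))
}

# Number of (near-)zero eigenvalues of a symmetric PSD operator.
kernel_dim <- function(L, tol = 1e-8) {
  L <- as.matrix(L)
  if (nrow(L) == 0L) return(0L)
  sum(eigen(L, symmetric = TRUE, only.values = TRUE)$values < tol)
}

path_complex <- function(ids) {
  edges <- lapply(seq_len(length(ids) - 1L), function(i) ids[c(i, i + 1L)])
  load_complex(edges, ids)
}
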