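test_that("q0 score reproduces the worked path-graph value and degeneracies", {
  path <- path_complex(c("a", "b", "c"))
  ops <- boundary_matrices(path)
  expect_equal(score_q0(c(1, 0, 0), ops), 4 / 3)
  expect_warning(s <- score_q0(c(2, 2, 2), ops), "undefined")
  expect_true(is.na(s))
  expect_error(score_q0(c(1, 0), ops), "does not match")

  # no edges: every score is undefined rather than an error
  lone <- load_complex(list(), c("a", "b"))
  expect_warning(s0 <- score_q0(c(1, 0), boundary_matrices(lone)))
  expect_true(is.na(s0))
})

test_that("q0 score agrees with the dense graph Laplacian score oracle", {
  for (case in 1:12) {
    n <- sample(5:40, 1)
    rc <- random_vr_complex(n, seed = 700 + case)
    cx <- rc$complex
    ops0 <- boundary_matrices(cx)
    if (ops0$n_edges == 0) next
    set.seed(case)
    w <- runif(nrow(cx$edges), 0.2, 3)
    ops <- boundary_matrices(cx, edge_weights = w)
    W <- matrix(0, n, n)
    W[cx$edges] <- w
    W <- W + t(W)
    f <- rnorm(n)
    expect_equal(score_q0(f, ops), oracle_laplacian_score(f, W),
                 tolerance = 1e-10)
  }
})

test_that("a clique-localized indicator outscores an equally variable scattered one", {
  # 3-clique {a,b,c} chained to path d-e-f; both indicators have 3 ones
  cx <- load_complex(list(c("a", "b", "c"), c("c", "d"), c("d", "e"),
                          c("e", "f")),
                     letters[1:6])
  ops <- boundary_matrices(cx)
  clique_ind <- c(1, 1, 1, 0, 0, 0)
  scattered_ind <- c(1, 0, 0, 1, 0, 1)
  W <- matrix(0, 6, 6); W[cx$edges] <- 1; W <- W + t(W)
  expect_lt(score_q0(clique_ind, ops), score_q0(scattered_ind, ops))
  expect_equal(score_q0(clique_ind, ops), oracle_laplacian_score(clique_ind, W),
               tolerance = 1e-12)
  expect_equal(score_q0(scattered_ind, ops),
               oracle_laplacian_score(scattered_ind, W), tolerance = 1e-12)
})

test_that("edge lifting averages endpoint values in canonical edge order", {
  edge <- load_complex(list(c("u", "v")), c("u", "v"))
  expect_equal(lift_to_edges(c(2, 4), edge), 3)

  path <- path_complex(c("a", "b", "c", "d"))
  g <- lift_to_edges(c(1, 1, 0, 0), path)   # edges ab, bc, cd
  expect_equal(g, c(1, 0.5, 0))

  lone <- load_complex(list(), c("a", "b"))
  expect_length(lift_to_edges(c(1, 2), lone), 0)
})

test_that("q1 score is zero for harmonic cochains and matches dense oracles", {
  hollow <- load_complex(list(c("a", "b"), c("b", "c"), c("a", "c")),
                         c("a", "b", "c"))
  filled <- load_complex(list(c("a", "b", "c")), c("a", "b", "c"))
  cycle <- c(1, -1, 1)                      # edges ab, ac, bc
  expect_equal(score_q1(cycle, boundary_matrices(hollow)), 0)
  expect_equal(score_q1(cycle, boundary_matrices(filled)), 3)

  ref <- oracle_boundaries(filled)
  L1 <- t(ref$d1) %*% ref$d1 + ref$d2 %*% t(ref$d2)
  expect_equal(score_q1(cycle, boundary_matrices(filled)),
               as.numeric(t(cycle) %*% L1 %*% cycle) / sum(cycle^2))

  expect_warning(s <- score_q1(c(0, 0, 0), boundary_matrices(hollow)),
                 "undefined")
  expect_true(is.na(s))
})

test_that("a cycle cochain outscores a pendant-edge cochain", {
  # hollow square a-b-c-d plus pendant edge d-e
  cx <- load_complex(list(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"),
                          c("d", "e")),
                     letters[1:5])
  ops <- boundary_matrices(cx)
  ekey <- apply(cx$edges, 1, function(r) paste(cx$vertices[r], collapse = ""))
  cycle <- numeric(ops$n_edges)
  cycle[match(c("ab", "bc", "cd", "ad"), ekey)] <- c(1, 1, 1, -1)
  pendant <- numeric(ops$n_edges)
  pendant[match("de", ekey)] <- 1
  expect_equal(score_q1(cycle, ops), 0)
  expect_lt(score_q1(cycle, ops), score_q1(pendant, ops))
})

test_that("scores are invariant to relabeling, scaling and (for q0) shifts", {
  rc <- random_vr_complex(15, seed = 901)
  cx <- rc$complex
  ops <- boundary_matrices(cx)
  set.seed(1); f <- rnorm(15)
  s <- score_q0(f, ops)
  expect_gte(s, 0)
  expect_equal(score_q0(3.7 * f, ops), s)
  expect_equal(score_q0(f + 11, ops), s)

  # relabeling: reorder vertices by root distance, permute f accordingly
  cx2 <- orient_by_root(cx, cx$vertices[7], "metric_distance", rc$dist)
  f2 <- f[match(cx2$vertices, cx$vertices)]
  expect_equal(score_q0(f2, boundary_matrices(cx2)), s)

  # q1: scale invariance (the lift itself depends on the vertex ordering,
  # which is why orient_by_root exists; reorientation invariance with the
  # simultaneous sign flip is tested separately)
  if (ops$n_edges > 0) {
    g <- lift_to_edges(f, cx)
    s1 <- score_q1(g, ops)
    expect_gte(s1, 0)
    expect_equal(score_q1(-2 * g, ops), s1)
  }
})

test_that("q1 score is invariant under single-edge reorientation with sign flip", {
  cx <- load_complex(list(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d")),
                     letters[1:4])
  ops <- boundary_matrices(cx)
  set.seed(8); g <- rnorm(ops$n_edges)
  s <- score_q1(g, ops)
  # flipping an edge's orientation negates its row of d1/column pattern;
  # equivalently L1 conjugated by a diagonal sign matrix: flip cochain too
  for (e in seq_len(ops$n_edges)) {
    Sg <- g; Sg[e] <- -Sg[e]
    Fl <- Matrix::Diagonal(x = replace(rep(1, ops$n_edges), e, -1))
    L1f <- Fl %*% ops$L1 %*% Fl
    expect_equal(as.numeric(t(Sg) %*% as.matrix(L1f %*% Sg)) / sum(Sg^2), s)
  }
})

test_that("the harmonic space is nontrivial exactly when b1 > 0", {
  for (case in 1:8) {
    cx <- random_vr_complex(sample(8:20, 1), seed = 1100 + case)$complex
    ops <- boundary_matrices(cx)
    if (ops$n_edges == 0) next
    b1 <- betti_numbers(cx)[["b1"]]
    ev <- eigen(as.matrix(ops$L1), symmetric = TRUE)
    expect_equal(sum(ev$values < 1e-8), as.integer(b1))
    if (b1 > 0) {
      h <- ev$vectors[, which.min(ev$values)]
      expect_equal(score_q1(h, ops), 0, tolerance = 1e-9)
    }
  }
})

test_that("bivariate score reduces, signs adjacency and zeroes disconnection", {
  p4 <- path_complex(letters[1:4])
  ops <- boundary_matrices(p4)
  f <- c(1, 1, 0, 0); g <- c(0, 0, 1, 1)
  expect_equal(score_bivariate_q0(f, f, ops), score_q0(f, ops))
  expect_lt(score_bivariate_q0(f, g, ops), 0)
  expect_equal(score_bivariate_q0(f, g, ops), score_bivariate_q0(g, f, ops))

  disc <- load_complex(list(c("a", "b"), c("c", "d")), letters[1:4])
  dops <- boundary_matrices(disc)
  expect_equal(score_bivariate_q0(c(1, 1, 0, 0), c(0, 0, 1, 1), dops), 0)

  expect_warning(s <- score_bivariate_q0(c(1, 1, 1, 1), g, ops), "undefined")
  expect_true(is.na(s))
})

test_that("node aggregation averages member samples and validates membership", {
  vals <- c(s1 = 1, s2 = 10, s3 = 3)
  expect_equal(aggregate_to_nodes(vals, list(n1 = c("s1", "s3"))),
               c(n1 = 2))
  expect_equal(aggregate_to_nodes(vals, list(n1 = "s2")), c(n1 = 10))
  expect_error(aggregate_to_nodes(vals, list(n1 = character(0))),
               "no member")
  expect_error(aggregate_to_nodes(vals, list(n1 = c("s1", "nope"))),
               "unknown sample 'nope'")

  m <- rbind(f1 = vals, f2 = 2 * vals)
  out <- aggregate_to_nodes(m, list(a = c("s1", "s3"), b = "s2"))
  expect_equal(out, rbind(f1 = c(a = 2, b = 10), f2 = c(a = 4, b = 20)))
})

test_that("detection-fraction filter applies strict bounds", {
  expr <- rbind(
    in_30pct = as.numeric(seq_len(100) <= 30),
    in_25pct = as.numeric(seq_len(100) <= 25),
    in_10pct = as.numeric(seq_len(100) <= 10),
    in_1pct = as.numeric(seq_len(100) <= 1),
    silent = rep(0, 100)
  )
  expect_equal(feature_filter(expr, 0.01, 0.25), "in_10pct")
  expect_error(feature_filter(expr, 0.5, 0.2), "min_frac < max_frac")
})
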