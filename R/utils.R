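# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.  All stochastic entry points go through this, so no
# function touches global state beyond its own call.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("'seed' must be a single finite integer")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

# Coerce a feature-by-sample input (matrix or data frame) to a plain numeric
# matrix with unique feature and sample ids.
as_feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.null(dim(features)) && is.numeric(features)) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list("feature_1", names(features)))
  }
  if (!is.matrix(features) || !is.numeric(features)) {
    stopf("'features' must be a numeric feature-by-sample matrix")
  }
  if (any(!is.finite(features))) {
    stopf("feature values must all be finite")
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("feature_", seq_len(nrow(features)))
  }
  dup <- anyDuplicated(rownames(features))
  if (dup) stopf("duplicate feature id: '%s'", rownames(features)[dup])
  features
}

# Validate a square symmetric dissimilarity matrix.
validate_distance_matrix <- function(d, tol = 1e-8) {
  if (is.data.frame(d)) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stopf("a distance matrix must be a square numeric matrix")
  }
  if (any(!is.finite(d))) stopf("distance matrix entries must be finite")
  if (any(d < -tol)) stopf("distance matrix entries must be nonnegative")
  if (max(abs(d - t(d))) > tol) stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > tol)) stopf("distance matrix diagonal must be zero")
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}
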