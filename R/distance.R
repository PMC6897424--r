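#' Pairwise dissimilarities between samples
#'
#' Computes a symmetric sample-by-sample dissimilarity matrix from a
#' sample-by-feature data matrix.  The Pearson correlation distance
#' `1 - r` (range `[0, 2]`) is the usual choice for expression profiles;
#' Euclidean distance suits low-dimensional embeddings or spatial
#' coordinates, and cosine distance is provided for sparse nonnegative data.
#'
#' @param data Numeric sample-by-feature matrix (rows are samples).
#' @param metric One of `"pearson_correlation"`, `"euclidean"`, `"cosine"`.
#'
#' @return A square numeric matrix with zero diagonal, symmetric and
#'   nonnegative, with sample ids as dimnames (taken from `rownames(data)`
#'   or generated as `s1, s2, ...`).
#'
#' @details Correlation and cosine metrics require every sample to have,
#'   respectively, nonzero variance and nonzero norm; offending samples are
#'   reported by name.
#'
#' @examples
#' x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' compute_distance_matrix(x, "pearson_correlation")["a", "b"]  # 2
#' @export
compute_distance_matrix <- function(data,
                                    metric = c("pearson_correlation",
                                               "euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("'data' must be a numeric sample-by-feature matrix")
  }
  if (nrow(data) < 2L) stopf("at least 2 samples are required")
  if (any(!is.finite(data))) stopf("'data' must be finite")
  ids <- rownames(data) %||% paste0("s", seq_len(nrow(data)))

  d <- switch(metric,
    pearson_correlation = {
      if (ncol(data) < 2L) {
        stopf("correlation distance requires at least 2 features")
      }
      centered <- data - rowMeans(data)
      ss <- rowSums(centered^2)
      bad <- which(ss <= 0)
      if (length(bad)) {
        stopf("sample '%s' has zero variance; correlation distance undefined",
              ids[bad[1L]])
      }
      1 - stats::cor(t(data))
    },
    euclidean = as.matrix(stats::dist(data, method = "euclidean")),
    cosine = {
      nrm <- sqrt(rowSums(data^2))
      bad <- which(nrm <= 0)
      if (length(bad)) {
        stopf("sample '%s' has zero norm; cosine distance undefined",
              ids[bad[1L]])
      }
      1 - (data %*% t(data)) / outer(nrm, nrm)
    }
  )
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}
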