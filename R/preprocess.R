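#' Library-size-normalized log expression
#'
#' Scales each cell's counts to a common total (counts per `scale` total
#' molecules) and applies `log1p`.  Correlation distances computed from raw
#' log counts mainly reflect per-cell library size; normalizing first makes
#' the metric structure reflect expression composition instead, which is
#' the standard preprocessing before building an expression complex.
#'
#' @param counts Gene-by-cell count matrix.
#' @param scale Target total per cell (default `1e4`).
#'
#' @return Gene-by-cell matrix of `log1p` normalized expression values.
#' @export
normalize_log_counts <- function(counts, scale = 1e4) {
  counts <- as_feature_matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stopf("cell '%s' has zero total count",
          colnames(counts)[which(totals <= 0)[1L]])
  }
  log1p(sweep(counts, 2L, totals / scale, "/"))
}
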