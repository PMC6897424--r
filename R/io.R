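# File formats: delimited feature/distance matrices, Matrix Market with id
# sidecars, the complex JSON dialect, and results tables.  All on-disk ids
# are names; internal integer indices are never serialized.

read_delimited_matrix <- function(path, sep) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(raw[[1L]])
  dup <- anyDuplicated(ids)
  if (dup) stopf("duplicate row id '%s' in '%s'", ids[dup], path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1L)))[1L]
    stopf("non-numeric values in column '%s' of '%s'",
          colnames(raw)[-1L][bad], path)
  }
  rownames(m) <- ids
  m
}

#' Read a feature matrix from TSV, CSV or Matrix Market files
#'
#' Delimited input is a features-by-samples table whose header row holds
#' sample ids and whose first column holds feature ids.  Matrix Market
#' input is a sparse features-by-samples matrix accompanied by two
#' plain-text id files (one id per line); entries absent from the sparse
#' file are read as 0.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param feature_file,sample_file Id sidecar files, required for
#'   `format = "mtx"`.
#'
#' @return Numeric feature-by-sample matrix with ids as dimnames.
#' @export
load_feature_matrix <- function(path, format = c("tsv", "csv", "mtx"),
                                feature_file = NULL, sample_file = NULL) {
  format <- match.arg(format)
  if (format %in% c("tsv", "csv")) {
    m <- read_delimited_matrix(path, sep = if (format == "tsv") "\t" else ",")
    return(as_feature_matrix(m))
  }
  if (is.null(feature_file) || is.null(sample_file)) {
    stopf("'mtx' format requires 'feature_file' and 'sample_file'")
  }
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  m <- as.matrix(Matrix::readMM(path))
  fids <- readLines(feature_file)
  sids <- readLines(sample_file)
  if (length(fids) != nrow(m)) {
    stopf("'%s' lists %d feature ids but the matrix has %d rows",
          feature_file, length(fids), nrow(m))
  }
  if (length(sids) != ncol(m)) {
    stopf("'%s' lists %d sample ids but the matrix has %d columns",
          sample_file, length(sids), ncol(m))
  }
  dup <- anyDuplicated(fids)
  if (dup) stopf("duplicate feature id '%s' in '%s'", fids[dup], feature_file)
  dimnames(m) <- list(fids, sids)
  as_feature_matrix(m)
}

#' Write a feature matrix to TSV, CSV or Matrix Market files
#'
#' Inverse of [load_feature_matrix()].
#'
#' @param x Feature-by-sample numeric matrix with dimnames.
#' @param path Output matrix file.
#' @inheritParams load_feature_matrix
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path, format = c("tsv", "csv", "mtx"),
                                 feature_file = NULL, sample_file = NULL) {
  format <- match.arg(format)
  x <- as_feature_matrix(x)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(feature_file) || is.null(sample_file)) {
      stopf("'mtx' format requires 'feature_file' and 'sample_file'")
    }
    Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"), path)
    writeLines(rownames(x), feature_file)
    writeLines(colnames(x), sample_file)
  }
  invisible(path)
}

#' Read / write a square distance matrix as delimited text
#'
#' The on-disk format is a square table with a header row and a first
#' column both holding the sample ids.
#'
#' @param path File path.
#' @param sep Field separator (tab by default).
#' @return `read_distance_matrix()` returns the validated matrix;
#'   `write_distance_matrix()` invisibly returns `path`.
#' @export
read_distance_matrix <- function(path, sep = "\t") {
  m <- read_delimited_matrix(path, sep = sep)
  if (!identical(rownames(m), colnames(m))) {
    stopf("row and column ids of '%s' do not match", path)
  }
  validate_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param d Square symmetric distance matrix.
#' @export
write_distance_matrix <- function(d, path, sep = "\t") {
  d <- validate_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a simplicial complex in the JSON dialect
#'
#' The dialect is
#' `{"vertices": [ids...], "maximal_simplices": [[ids...], ...],
#' "epsilon": number|null}`; the order of `"vertices"` is the orientation
#' order.  On writing, the maximal simplices are the triangles, the edges
#' not contained in any triangle, and the isolated vertices.
#'
#' @param path File path.
#' @return `read_complex_json()` returns a `simplicial_complex`;
#'   `write_complex_json()` invisibly returns `path`.
#' @export
read_complex_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$vertices)) stopf("'%s' has no \"vertices\" entry", path)
  vertices <- as.character(unlist(obj$vertices, use.names = FALSE))
  simplices <- lapply(obj$maximal_simplices %||% list(), function(s) {
    as.character(unlist(s, use.names = FALSE))
  })
  eps <- obj$epsilon
  if (!is.null(eps)) eps <- as.numeric(eps)
  load_complex(simplices, vertices, epsilon = eps)
}

#' @rdname read_complex_json
#' @param complex A `simplicial_complex`.
#' @export
write_complex_json <- function(complex, path) {
  stopifnot(inherits(complex, "simplicial_complex"))
  v <- complex$vertices
  edges <- complex$edges
  tris <- complex$triangles
  in_tri <- rep(FALSE, nrow(edges))
  if (nrow(tris) > 0L && nrow(edges) > 0L) {
    ekey <- paste(edges[, 1L], edges[, 2L])
    tkey <- c(paste(tris[, 1L], tris[, 2L]), paste(tris[, 1L], tris[, 3L]),
              paste(tris[, 2L], tris[, 3L]))
    in_tri <- ekey %in% tkey
  }
  in_edge <- rep(FALSE, length(v))
  if (nrow(edges) > 0L) in_edge[unique(as.integer(edges))] <- TRUE
  maximal <- c(
    lapply(seq_len(nrow(tris)), function(i) v[tris[i, ]]),
    lapply(which(!in_tri), function(i) v[edges[i, ]]),
    lapply(which(!in_edge), function(i) v[i])
  )
  obj <- list(vertices = as.list(v),
              maximal_simplices = lapply(maximal, as.list),
              epsilon = complex$epsilon)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                              digits = NA),
             path)
  invisible(path)
}

#' Write a score table to TSV
#'
#' Writes the output of [score_table()] or [pair_score_table()] with
#' missing scores rendered as `NA` and row order preserved.
#'
#' @param results Nonempty data frame of results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stopf("'results' must be a nonempty data frame")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: '%s'", dir)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname save_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
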