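#' Expression matrix container
#'
#' A light S3 wrapper around a sparse (or dense) features-by-cells matrix of
#' non-negative values, carrying unique feature ids, display symbols (which
#' may repeat on disk and are de-duplicated at read time) and cell barcodes.
#' Raw objects hold integer UMI/read counts (`normalized = FALSE`); after
#' [log_normalize()] they hold log-normalized expression.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, features in rows,
#'   cells in columns, all entries `>= 0`.
#' @param feature_ids character vector of unique primary identifiers, one per
#'   row (e.g. Ensembl ids). Duplicates are made unique with `.1`, `.2`, ...
#'   suffixes.
#' @param feature_symbols character vector of display symbols, one per row;
#'   defaults to `feature_ids`. Duplicates are likewise suffixed.
#' @param cell_ids character vector of unique cell barcodes, one per column.
#' @param normalized logical flag; `FALSE` for raw counts.
#'
#' @return An object of class `expr_mat` with elements `values`,
#'   `feature_ids`, `feature_symbols`, `cell_ids`, `normalized`.
#' @export
expr_mat <- function(values, feature_ids = rownames(values),
                     feature_symbols = NULL, cell_ids = colnames(values),
                     normalized = FALSE) {
  if (is.null(feature_ids)) {
    feature_ids <- paste0("feature", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell", seq_len(ncol(values)))
  }
  if (is.null(feature_symbols)) feature_symbols <- feature_ids
  feature_ids <- make.unique(as.character(feature_ids), sep = ".")
  feature_symbols <- make.unique(as.character(feature_symbols), sep = ".")
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) [", length(feature_ids),
         "] != number of rows [", nrow(values), "]", call. = FALSE)
  }
  if (length(feature_symbols) != nrow(values)) {
    stop("length(feature_symbols) != number of rows", call. = FALSE)
  }
  if (length(cell_ids) != ncol(values)) {
    stop("length(cell_ids) [", length(cell_ids),
         "] != number of columns [", ncol(values), "]", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique", call. = FALSE)
  if (min_value(values) < 0) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(
    list(values = values, feature_ids = feature_ids,
         feature_symbols = feature_symbols, cell_ids = cell_ids,
         normalized = isTRUE(normalized)),
    class = "expr_mat"
  )
}

min_value <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    v <- x@x
    if (length(v) == 0) 0 else min(0, min(v))
  } else {
    min(x)
  }
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "log-normalized" else "raw counts"))
  nz <- Matrix::nnzero(x$values)
  cat(sprintf("  non-zero entries: %d (%.1f%%)\n", nz,
              100 * nz / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Subset an expression matrix by feature and/or cell
#'
#' @param x an [expr_mat].
#' @param features integer, logical or character index into the features.
#' @param cells integer, logical or character index into the cells.
#' @return The subsetted [expr_mat].
#' @export
subset_features <- function(x, features = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  ri <- if (is.null(features)) seq_len(nrow(x$values)) else features
  ci <- if (is.null(cells)) seq_len(ncol(x$values)) else cells
  if (is.character(ri)) ri <- match(ri, x$feature_ids)
  if (anyNA(ri)) stop("unknown feature id(s) in subset", call. = FALSE)
  if (is.logical(ri)) ri <- which(ri)
  vals <- x$values[ri, ci, drop = FALSE]
  expr_mat(vals,
           feature_ids = x$feature_ids[ri],
           feature_symbols = x$feature_symbols[ri],
           cell_ids = colnames(vals),
           normalized = x$normalized)
}

#' Read a count matrix from standard single-cell formats
#'
#' Supports the 10x Genomics directory layout (Matrix Market `matrix.mtx`
#' plus `features.tsv`/`genes.tsv` and `barcodes.tsv`, optionally gzipped)
#' and dense delimited text with features in rows. The matrix is always
#' returned features-by-cells; an on-disk matrix stored cells-by-features
#' (detected from the companion file lengths) is transposed.
#'
#' @param path file (csv/tsv) or directory (mtx_dir) to read.
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @return An [expr_mat] with `normalized = FALSE`.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input path does not exist: ", path, call. = FALSE)
  }
  if (format == "mtx_dir") read_mtx_dir(path) else read_dense(path, format)
}

find_companion <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  }
  NULL
}

read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) {
    stop("mtx_dir format expects a directory: ", dir, call. = FALSE)
  }
  mtx <- find_companion(dir, "matrix.mtx")
  feat <- find_companion(dir, c("features.tsv", "genes.tsv"))
  bc <- find_companion(dir, "barcodes.tsv")
  missing <- c(
    if (is.null(mtx)) "matrix.mtx(.gz)",
    if (is.null(feat)) "features.tsv(.gz)/genes.tsv(.gz)",
    if (is.null(bc)) "barcodes.tsv(.gz)"
  )
  if (length(missing)) {
    stop("mtx directory ", dir, " is missing companion file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- Matrix::readMM(mtx)
  ft <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  bt <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(ft[[1]])
  syms <- if (ncol(ft) >= 2) as.character(ft[[2]]) else ids
  cells <- as.character(bt[[1]])
  if (nrow(m) != length(ids) && ncol(m) == length(ids) &&
      nrow(m) == length(cells)) {
    m <- Matrix::t(m)  # stored cells x features; coerce to features x cells
  }
  if (nrow(m) != length(ids)) {
    stop("matrix has ", nrow(m), " feature rows but ", length(ids),
         " entries in the feature file: integrity error", call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop("matrix has ", ncol(m), " cell columns but ", length(cells),
         " entries in the barcode file: integrity error", call. = FALSE)
  }
  expr_mat(m, feature_ids = ids, feature_symbols = syms, cell_ids = cells,
           normalized = FALSE)
}

read_dense <- function(path, format) {
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  expr_mat(Matrix::Matrix(m, sparse = TRUE), feature_ids = ids,
           feature_symbols = ids, cell_ids = colnames(df)[-1],
           normalized = FALSE)
}

#' Write an expression matrix as delimited text or a 10x-style directory
#'
#' Round-trip companion to [read_counts()]; used mostly for fixtures and for
#' exporting small matrices.
#'
#' @param x an [expr_mat].
#' @param path output file (csv/tsv) or directory (mtx_dir).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_mat"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x$values, file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(x$feature_ids, x$feature_symbols),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(x$cell_ids), file.path(path, "barcodes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = x$feature_ids,
                     as.matrix(x$values), check.names = FALSE)
    colnames(df) <- c("gene", x$cell_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Log-normalize a count matrix
#'
#' Each cell is scaled to a common library size and log-transformed:
#' `out[g, c] = ln(1 + count[g, c] / colsum(c) * scale_factor)`. Zeros map to
#' zeros, so sparsity is preserved.
#'
#' @param mat an [expr_mat] with `normalized = FALSE`.
#' @param scale_factor positive library-size target (default `1e4`).
#' @return An [expr_mat] with `normalized = TRUE`.
#' @export
log_normalize <- function(mat, scale_factor = 1e4) {
  stopifnot(inherits(mat, "expr_mat"))
  if (mat$normalized) stop("matrix is already normalized", call. = FALSE)
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be a positive number", call. = FALSE)
  }
  totals <- Matrix::colSums(mat$values)
  if (any(totals == 0)) {
    bad <- mat$cell_ids[totals == 0]
    stop("cells with zero total count cannot be normalized: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  v <- mat$values
  # operate on the non-zero slots only: log1p(0) == 0 keeps the pattern
  percol <- rep.int(totals, diff(v@p))
  v@x <- log1p(v@x / percol * scale_factor)
  out <- mat
  out$values <- v
  out$normalized <- TRUE
  out
}
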