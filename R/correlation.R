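#' Gene-gene Pearson correlation matrix
#'
#' Computes the dense Pearson correlation of every gene pair across all
#' cells, via centered cross-products so that the sparse input is never
#' densified cell-wise. The result is symmetric with a unit diagonal and is
#' the substrate for the correlation-range score, stepwise regression and
#' guilt-by-association.
#'
#' @param mat a log-normalized [expr_mat].
#' @return A list of class `ggc_matrix` with `values` (p x p dense symmetric
#'   matrix) and `gene_index` (feature ids).
#' @export
compute_ggc <- function(mat) {
  stopifnot(inherits(mat, "expr_mat"))
  if (!mat$normalized) {
    stop("compute_ggc expects a log-normalized matrix; call log_normalize()",
         call. = FALSE)
  }
  x <- mat$values
  n <- ncol(x)
  if (n < 2) stop("need at least 2 cells to correlate", call. = FALSE)
  mu <- Matrix::rowMeans(x)
  # sample covariance from the uncentered cross-product:
  #   cov = (X X^T - n mu mu^T) / (n - 1)
  cp <- as.matrix(Matrix::tcrossprod(x))
  cv <- (cp - n * tcrossprod(mu)) / (n - 1)
  sd <- sqrt(diag(cv))
  zero_var <- sd <= .Machine$double.eps * sqrt(n)
  if (any(zero_var)) {
    stop("zero-variance gene(s) cannot be correlated: ",
         paste(utils::head(mat$feature_ids[zero_var], 10), collapse = ", "),
         call. = FALSE)
  }
  r <- cv / tcrossprod(sd)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(mat$feature_ids, mat$feature_ids)
  structure(list(values = r, gene_index = mat$feature_ids),
            class = "ggc_matrix")
}

#' @export
print.ggc_matrix <- function(x, ...) {
  cat(sprintf("<ggc_matrix> %d x %d gene-gene Pearson correlations\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Correlation range score
#'
#' For each gene `i`, the third-largest value of its correlation column
#' (diagonal included, i.e. the second-largest non-self correlation) minus
#' 0.75 times the column minimum. The positive end of the range is the
#' dominant term; the down-weighted negative end still rewards genes that
#' are strongly anti-correlated with another expression signature. Using the
#' second-largest rather than the largest non-self correlation guards
#' against artefactual perfect correlations between genes with overlapping
#' exons.
#'
#' @param ggc a `ggc_matrix` (from [compute_ggc()]) with at least 3 genes.
#' @return Named numeric vector of per-gene scores.
#' @export
correlation_range <- function(ggc) {
  stopifnot(inherits(ggc, "ggc_matrix"))
  v <- ggc$values
  p <- nrow(v)
  if (p < 3) {
    stop("correlation range needs at least 3 genes (third-largest value)",
         call. = FALSE)
  }
  max3 <- apply(v, 2, function(col) sort(col, decreasing = TRUE)[3])
  mins <- apply(v, 2, min)
  stats::setNames(max3 - 0.75 * mins, ggc$gene_index)
}

#' Bin genes by mean expression
#'
#' Equal-frequency bins over per-gene mean (normalized) expression, so that
#' the correlation-range score can be standardized against genes of similar
#' expression level (technical noise in scRNA-seq tracks mean expression).
#' Bin sizes differ by at most one; ties in the mean are broken by the
#' original gene order, which makes the binning deterministic.
#'
#' @param mat an [expr_mat].
#' @param n_bins number of bins (default 20); must not exceed the gene count.
#' @return Integer vector of bin labels in `1..n_bins`, named by feature id.
#' @export
bin_by_mean_expression <- function(mat, n_bins = 20) {
  stopifnot(inherits(mat, "expr_mat"))
  p <- nrow(mat$values)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  if (n_bins > p) {
    stop("n_bins (", n_bins, ") exceeds the number of genes (", p, ")",
         call. = FALSE)
  }
  means <- Matrix::rowMeans(mat$values)
  ord <- order(means)  # radix sort: stable, ties keep gene order
  sizes <- rep(p %/% n_bins, n_bins)
  extra <- p %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- integer(p)
  labels[ord] <- rep(seq_len(n_bins), times = sizes)
  stats::setNames(labels, mat$feature_ids)
}

#' Binned z-score of the correlation range
#'
#' Within each expression bin, standardizes the correlation-range score by
#' the bin mean and bin sample standard deviation. A bin with zero spread
#' assigns z = 0 to all its members; singleton bins are an error (reduce
#' `n_bins`).
#'
#' @param c_scores per-gene correlation-range scores.
#' @param bins per-gene integer bin labels, same length.
#' @return Numeric vector of z-scores, named like `c_scores`.
#' @export
correlation_range_zscore <- function(c_scores, bins) {
  if (length(c_scores) != length(bins)) {
    stop("c_scores and bins must have the same length", call. = FALSE)
  }
  tab <- table(bins)
  if (any(tab < 2)) {
    stop("bin(s) with fewer than 2 genes: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         "; reduce n_bins", call. = FALSE)
  }
  z <- numeric(length(c_scores))
  for (b in unique(bins)) {
    i <- which(bins == b)
    mu <- mean(c_scores[i])
    sdv <- stats::sd(c_scores[i])
    z[i] <- if (sdv > 0) (c_scores[i] - mu) / sdv else 0
  }
  stats::setNames(z, names(c_scores))
}

#' Select candidate feature genes by z-score threshold
#'
#' A gene is a candidate iff its binned correlation-range z-score strictly
#' exceeds the threshold; genes with `z <= z_threshold` are filtered out.
#'
#' @param z per-gene z-scores.
#' @param z_threshold exclusive lower bound (default 0.7).
#' @return Logical mask, named like `z`.
#' @export
select_candidates <- function(z, z_threshold = 0.7) {
  mask <- z > z_threshold
  if (!any(mask)) {
    stop("no gene exceeds z_threshold = ", z_threshold,
         "; lower the threshold", call. = FALSE)
  }
  mask
}

#' Per-gene correlation-range score table
#'
#' Convenience wrapper running [compute_ggc()], [correlation_range()],
#' [bin_by_mean_expression()], [correlation_range_zscore()] and
#' [select_candidates()] and collecting the results in one tibble.
#'
#' @param mat a log-normalized [expr_mat].
#' @param n_bins number of expression bins (default 20).
#' @param z_threshold candidate threshold on the z-score (default 0.7).
#' @return A tibble with columns `gene`, `mean_expr`, `bin`, `cor_range`,
#'   `zscore`, `candidate`, plus the `ggc_matrix` as attribute `"ggc"`.
#' @export
score_gene_correlations <- function(mat, n_bins = 20, z_threshold = 0.7) {
  ggc <- compute_ggc(mat)
  cr <- correlation_range(ggc)
  bins <- bin_by_mean_expression(mat, n_bins = n_bins)
  z <- correlation_range_zscore(cr, bins)
  mask <- select_candidates(z, z_threshold = z_threshold)
  out <- tibble::tibble(
    gene = mat$feature_ids,
    mean_expr = as.numeric(Matrix::rowMeans(mat$values)),
    bin = as.integer(bins),
    cor_range = as.numeric(cr),
    zscore = as.numeric(z),
    candidate = as.logical(mask)
  )
  attr(out, "ggc") <- ggc
  out
}
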