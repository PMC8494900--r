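#' Silhouette index of a labeled embedding
#'
#' Mean over cells of `(b - a) / max(a, b)`, with `a` the mean Euclidean
#' distance to same-cluster cells (self excluded) and `b` the smallest mean
#' distance to any other cluster. Conventions for degenerate cells: a cell
#' in a singleton cluster scores 0, and `a = b = 0` (all relevant distances
#' zero) scores 0.
#'
#' @param M a `pc_embedding` or numeric matrix, cells in rows.
#' @param labels per-cell cluster labels (>= 2 distinct values).
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_index <- function(M, labels) {
  if (inherits(M, "pc_embedding")) M <- M$M
  labels <- as.character(labels)
  n <- nrow(M)
  if (length(labels) != n) {
    stop("labels must have one entry per cell", call. = FALSE)
  }
  ulab <- unique(labels)
  if (length(ulab) < 2) {
    stop("silhouette needs at least 2 distinct labels", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(M))
  s <- vapply(seq_len(n), function(i) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    if (length(same) == 0) return(0)  # singleton cluster
    a <- mean(dm[i, same])
    b <- min(vapply(setdiff(ulab, labels[i]), function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    m <- max(a, b)
    if (m == 0) 0 else (b - a) / m
  }, numeric(1))
  mean(s)
}

#' AUROC for recovering known DE genes
#'
#' Rank-based area under the ROC curve of per-gene scores against a boolean
#' ground truth, computed via the Wilcoxon mid-rank identity so ties are
#' handled by mid-ranks.
#'
#' @param scores per-gene numeric scores (higher = more likely DE).
#' @param truth per-gene logical ground truth; both classes must occur.
#' @return Scalar AUROC in `[0, 1]`.
#' @export
de_recovery_auroc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop("scores and truth must have the same length", call. = FALSE)
  }
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    stop("truth must contain both classes", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks on ties
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
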