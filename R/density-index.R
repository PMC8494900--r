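#' PCA embedding of cells on a feature set
#'
#' Restricts the matrix to the given features, z-scores each feature across
#' cells (zero mean, unit sd; zero-variance features are dropped with a
#' warning) and computes cell scores on the top `D` principal components.
#' Scores are centered per component by construction.
#'
#' @param mat a log-normalized [expr_mat].
#' @param features character vector of feature ids to embed on.
#' @param D number of principal components (default 20); clamped to
#'   `min(n_cells - 1, n_features)` with a warning if too large.
#' @param scale_features z-score features before PCA (default TRUE).
#' @return A list of class `pc_embedding`: `M` (N cells x D score matrix)
#'   and `component_variance`.
#' @export
pca_embed <- function(mat, features, D = 20, scale_features = TRUE) {
  stopifnot(inherits(mat, "expr_mat"))
  if (!mat$normalized) {
    stop("pca_embed expects a log-normalized matrix", call. = FALSE)
  }
  missing <- setdiff(features, mat$feature_ids)
  if (length(missing)) {
    stop("feature(s) not in the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- t(as.matrix(mat$values[match(features, mat$feature_ids), ,
                              drop = FALSE]))  # cells x features
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped before PCA",
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0) stop("no feature with nonzero variance", call. = FALSE)
  }
  d_max <- min(nrow(x) - 1, ncol(x))
  if (D > d_max) {
    warning("D = ", D, " clamped to ", d_max, call. = FALSE)
    D <- d_max
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_features, rank. = D)
  M <- pr$x[, seq_len(D), drop = FALSE]
  structure(list(M = unname(M), component_variance = pr$sdev[seq_len(D)]^2),
            class = "pc_embedding")
}

#' Root-mean-square pairwise cell distance
#'
#' For a column-centered embedding `M` of `N` cells, the RMS Euclidean
#' distance over all `N^2` ordered cell pairs (self-pairs included) reduces
#' to `sqrt(2/N) * ||M||_F`: the cross term vanishes because each component
#' has zero mean.
#'
#' @param M a `pc_embedding` or a column-centered numeric matrix (cells in
#'   rows).
#' @return Non-negative scalar `d_rms`.
#' @export
rms_pairwise_distance <- function(M) {
  if (inherits(M, "pc_embedding")) M <- M$M
  n <- nrow(M)
  if (is.null(n) || n == 0) stop("empty embedding", call. = FALSE)
  sqrt(2 / n) * norm(M, type = "F")
}

#' Mean k-nearest-neighbor distance
#'
#' Exact Euclidean kNN per cell (self excluded); returns the mean over cells
#' of each cell's mean distance to its `k` nearest neighbors.
#'
#' @param M a `pc_embedding` or numeric matrix (cells in rows).
#' @param k number of neighbors, `1 <= k <= N - 1`.
#' @return Non-negative scalar `k_m`.
#' @export
mean_knn_distance <- function(M, k = 10) {
  if (inherits(M, "pc_embedding")) M <- M$M
  n <- nrow(M)
  if (k < 1 || k >= n) {
    stop("k must satisfy 1 <= k <= N - 1 (N = ", n, ")", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(M))
  k_i <- vapply(seq_len(n), function(i) {
    mean(sort(dm[i, -i], partial = k)[seq_len(k)])
  }, numeric(1))
  mean(k_i)
}

#' Density index
#'
#' `DI = d_rms / k_m`: the RMS distance between random cell pairs divided by
#' the mean distance of a cell to its `k` nearest neighbors. When cells
#' aggregate into well-separated clumps, near-neighbor distances shrink
#' relative to random-pair distances and DI grows; DI is invariant to
#' rotation and uniform scaling of the embedding, like the silhouette index
#' it proxies.
#'
#' @param M a `pc_embedding` or column-centered numeric matrix.
#' @param k number of nearest neighbors (default 10).
#' @return Positive scalar DI.
#' @export
compute_density_index <- function(M, k = 10) {
  d_rms <- rms_pairwise_distance(M)
  k_m <- mean_knn_distance(M, k = k)
  if (k_m == 0) {
    stop("mean kNN distance is zero (duplicate embeddings); DI undefined",
         call. = FALSE)
  }
  d_rms / k_m
}

#' Default geometric grid of feature-set sizes
#'
#' Roughly `n_sizes` geometrically spaced integers from the seed-set size to
#' `max_size`, deduplicated.
#'
#' @param from smallest size (the seed-set size).
#' @param to largest size (number of ordered features, capped at 4000).
#' @param n_sizes target number of grid points (default 25).
#' @return Increasing integer vector.
#' @export
default_size_grid <- function(from, to, n_sizes = 25) {
  to <- min(to, 4000)
  if (to < from) stop("empty size grid: to < from", call. = FALSE)
  unique(round(exp(seq(log(from), log(to), length.out = n_sizes))))
}

#' Optimize the feature-set size by Density Index
#'
#' Evaluates DI on each prefix of the feature ordering listed in `sizes`
#' (PCA embedding recomputed per size) and returns the DI profile together
#' with the DI-maximizing size (first maximum on ties).
#'
#' @param mat a log-normalized [expr_mat].
#' @param ordering a `feature_ordering` from [expand_by_association()].
#' @param sizes increasing integer vector of prefix sizes; default
#'   [default_size_grid()] from `max(seed-set size, D)` to the ordering
#'   length. The lower anchor keeps the embedding dimension constant at `D`
#'   across the grid: below `D` features the dimension is clamped to the
#'   size, and DI values computed in different dimensions are not
#'   comparable (near-neighbor distances concentrate toward random-pair
#'   distances as dimension grows, inflating DI in low dimensions).
#' @param D number of principal components (default 20).
#' @param k nearest neighbors for DI (default 10).
#' @param scale_features z-score features before PCA (default TRUE).
#' @return A list of class `di_profile`: `profile` (tibble `size`, `di`),
#'   `optimal_size`, `k_used`, `D_used`.
#' @export
optimize_feature_size <- function(mat, ordering, sizes = NULL, D = 20,
                                  k = 10, scale_features = TRUE) {
  stopifnot(inherits(ordering, "feature_ordering"))
  feats <- ordering$ordering$gene
  if (is.null(sizes)) {
    lo <- min(max(length(ordering$seed_genes), D), length(feats))
    sizes <- default_size_grid(lo, length(feats))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0) stop("empty size grid", call. = FALSE)
  if (max(sizes) > length(feats)) {
    stop("size grid exceeds the number of ordered features", call. = FALSE)
  }
  if (min(sizes) < length(ordering$seed_genes)) {
    stop("size grid starts below the seed-set size", call. = FALSE)
  }
  di <- vapply(sizes, function(s) {
    emb <- suppressWarnings(
      pca_embed(mat, feats[seq_len(s)], D = D,
                scale_features = scale_features))
    compute_density_index(emb, k = k)
  }, numeric(1))
  structure(
    list(profile = tibble::tibble(size = sizes, di = di),
         optimal_size = sizes[which.max(di)], k_used = k, D_used = D),
    class = "di_profile"
  )
}

#' @export
print.di_profile <- function(x, ...) {
  cat(sprintf("<di_profile> %d sizes, optimum at %d features (DI = %.3f)\n",
              nrow(x$profile), x$optimal_size, max(x$profile$di)))
  invisible(x)
}
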