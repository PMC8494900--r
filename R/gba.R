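#' Guilt-by-association feature expansion
#'
#' Grows the seed set into a full ranked feature ordering: at each step the
#' not-yet-included candidate with the strongest (largest signed) Pearson
#' correlation to ANY gene already in the feature set is appended, so
#' membership propagates through the correlation network — a gene can be
#' admitted through a gene that itself was admitted earlier, not only
#' through a seed. The per-candidate running maximum is maintained
#' incrementally, making each step O(p).
#'
#' Ties in the maximum correlation break toward the smaller gene index
#' (position in `ggc$gene_index`), which makes the ordering deterministic.
#'
#' @param ggc a `ggc_matrix` over the candidate genes.
#' @param seeds character vector of seed gene ids, in their stepwise order.
#' @param max_size stop once the ordering reaches this size (default: all
#'   genes in `ggc`).
#' @return A list of class `feature_ordering`: `ordering`, a tibble with
#'   columns `rank`, `gene`, `is_seed`, `association_score` (`NA` for
#'   seeds; otherwise the correlation that admitted the gene), and
#'   `seed_genes`.
#' @export
expand_by_association <- function(ggc, seeds,
                                  max_size = length(ggc$gene_index)) {
  stopifnot(inherits(ggc, "ggc_matrix"))
  idx <- match(seeds, ggc$gene_index)
  if (anyNA(idx)) {
    stop("seed gene(s) not in the correlation matrix: ",
         paste(seeds[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicate seed genes", call. = FALSE)
  p <- length(ggc$gene_index)
  if (max_size < length(seeds)) {
    stop("max_size must be at least the number of seeds", call. = FALSE)
  }
  max_size <- min(max_size, p)
  v <- ggc$values
  n_append <- max_size - length(seeds)
  order_idx <- c(idx, integer(n_append))
  scores <- rep(NA_real_, max_size)
  in_set <- rep(FALSE, p)
  in_set[idx] <- TRUE
  # running max correlation from each candidate to the current feature set
  run_max <- if (length(idx) == 1) v[, idx] else apply(v[, idx, drop = FALSE], 1, max)
  run_max[in_set] <- -Inf
  k <- length(seeds)
  while (k < max_size) {
    j <- which.max(run_max)  # first max -> smallest index on ties
    k <- k + 1
    order_idx[k] <- j
    scores[k] <- run_max[j]
    in_set[j] <- TRUE
    run_max <- pmax(run_max, v[, j])
    run_max[in_set] <- -Inf
  }
  ordering <- tibble::tibble(
    rank = seq_len(max_size),
    gene = ggc$gene_index[order_idx],
    is_seed = seq_len(max_size) <= length(seeds),
    association_score = scores
  )
  structure(list(ordering = ordering, seed_genes = seeds),
            class = "feature_ordering")
}

#' @export
print.feature_ordering <- function(x, ...) {
  cat(sprintf("<feature_ordering> %d features (%d seeds + %d by association)\n",
              nrow(x$ordering), length(x$seed_genes),
              nrow(x$ordering) - length(x$seed_genes)))
  invisible(x)
}
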