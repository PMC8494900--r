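# Shared fixture builders and independent oracles used across test files.

# small dense count matrix wrapped as expr_mat
make_expr <- function(m, normalized = FALSE, ids = NULL, symbols = NULL) {
  if (is.null(rownames(m)) && is.null(ids)) {
    ids <- paste0("g", seq_len(nrow(m)))
  }
  expr_mat(Matrix::Matrix(m, sparse = TRUE), feature_ids = ids,
           feature_symbols = symbols, normalized = normalized)
}

# column-centered random embedding, cells in rows
rand_centered <- function(n, d) {
  scale(matrix(rnorm(n * d), n, d), center = TRUE, scale = FALSE)
}

# O(N^2) RMS pairwise distance over ordered pairs, self-pairs included
brute_rms_distance <- function(M) {
  d2 <- as.matrix(stats::dist(M))^2
  sqrt(mean(d2))
}

# per-gene variance explained by explicit rank-one regression (Frobenius drop)
brute_variance_explained <- function(G) {
  vapply(seq_len(ncol(G)), function(i) {
    g <- G[, i]
    if (sum(g^2) <= 1e-12) return(0)
    eps <- regress_out(G, i)
    norm(G, "F")^2 - norm(eps, "F")^2
  }, numeric(1))
}

# guilt-by-association oracle: rescan the full correlation submatrix at
# every step instead of keeping a running maximum
brute_gba <- function(ggc, seeds, max_size = length(ggc$gene_index)) {
  v <- ggc$values
  current <- match(seeds, ggc$gene_index)
  scores <- rep(NA_real_, length(current))
  while (length(current) < max_size) {
    remaining <- setdiff(seq_len(nrow(v)), current)
    best <- vapply(remaining, function(j) max(v[j, current]), numeric(1))
    pick <- remaining[which.max(best)]
    scores <- c(scores, max(best))
    current <- c(current, pick)
  }
  list(genes = ggc$gene_index[current], scores = scores)
}

ggc_from_matrix <- function(v, ids = paste0("g", seq_len(nrow(v)))) {
  dimnames(v) <- list(ids, ids)
  structure(list(values = v, gene_index = ids), class = "ggc_matrix")
}

# symmetric correlation-like matrix with unit diagonal from random data
rand_ggc <- function(p, n = 4 * p) {
  x <- matrix(rnorm(n * p), n, p)
  ggc_from_matrix(stats::cor(x))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "stepfeats", mustWork = TRUE)
}
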