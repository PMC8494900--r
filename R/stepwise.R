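#' Column-center a correlation matrix
#'
#' Subtracts each column mean. A symmetric input generally becomes
#' non-symmetric; that is expected — the stepwise regression operates on the
#' column-wise zero-centered matrix.
#'
#' @param G numeric matrix (typically `ggc_matrix$values`).
#' @return The centered matrix.
#' @export
center_columns <- function(G) {
  if (inherits(G, "ggc_matrix")) G <- G$values
  sweep(G, 2, colMeans(G), "-")
}

#' Variance explained by regressing out each gene
#'
#' For a column-centered matrix `G`, the variance each gene's column would
#' explain if regressed out of the whole matrix is computed for all genes
#' from the single product `X = t(G) %*% G`: with `x` the row of `X` for
#' gene `g`, `V[g] = sum(x^2) / (g . g)`, and `g . g` is the diagonal entry
#' of `X`. This equals the drop in squared Frobenius norm
#' `||G||_F^2 - ||eps||_F^2` after a rank-one least-squares regression on
#' that column. Genes with a zero-norm column get `V = 0`.
#'
#' @param G column-centered numeric matrix.
#' @return Numeric vector `V`, one entry per column of `G`.
#' @export
variance_explained_all <- function(G) {
  X <- crossprod(G)
  variance_from_crossprod(X)
}

variance_from_crossprod <- function(X, tol = 1e-12) {
  gtg <- diag(X)
  V <- rowSums(X^2) / ifelse(gtg > tol, gtg, 1)
  V[gtg <= tol] <- 0
  pmax(V, 0)  # clamp float negatives
}

#' Regress one gene's column out of the matrix
#'
#' Rank-one least-squares update: `eps = G - g %*% (t(g) %*% G) / (g . g)`,
#' where `g` is column `g_idx` of `G`. The residual's own column is zero and
#' the Pythagorean identity `||G||_F^2 = V + ||eps||_F^2` holds.
#'
#' @param G column-centered numeric matrix.
#' @param g_idx column index of the gene to regress out.
#' @return The residual matrix `eps`, same shape as `G`.
#' @export
regress_out <- function(G, g_idx) {
  g <- G[, g_idx]
  gtg <- sum(g^2)
  if (gtg <= 1e-12) {
    stop("column ", g_idx, " has (near-)zero norm; cannot regress",
         call. = FALSE)
  }
  w <- crossprod(g, G) / gtg   # 1 x p row of coefficients
  G - g %*% w
}

#' Elbow point of a scree curve
#'
#' Index of the point with maximum perpendicular distance to the chord from
#' the first to the last scree value. Ties break toward the smaller index,
#' so a constant or exactly linear scree returns 1.
#'
#' @param scree non-negative numeric vector, length >= 2.
#' @return Integer index into `scree`.
#' @export
elbow_point <- function(scree) {
  L <- length(scree)
  if (L < 2) stop("scree must have length >= 2", call. = FALSE)
  x <- seq_len(L)
  dy <- scree[L] - scree[1]
  dx <- L - 1
  d <- abs(dy * (x - 1) - dx * (scree - scree[1])) / sqrt(dy^2 + dx^2)
  which.max(d)  # first maximum on ties
}

#' Stepwise regression on the gene-gene correlation matrix
#'
#' Identifies a minimally redundant "seed" gene set. The correlation matrix
#' is column-centered once; at each step the gene explaining the most
#' variance in the current residual (see [variance_explained_all()]) is
#' regressed out. After `computed_steps` real steps the remaining scree
#' entries up to `total_steps` are assumed flat at the last computed value
#' (variance explained changes only marginally beyond that point), and the
#' seed-set size is the elbow of the resulting scree.
#'
#' Internally only `X = t(G) %*% G` is maintained: regressing out gene `j`
#' maps `X` to `X - outer(X[j, ], X[j, ]) / X[j, j]`, so each step is
#' O(p^2) after a single O(p^3) product.
#'
#' @param ggc a `ggc_matrix` over the candidate genes.
#' @param computed_steps number of real regression steps (default 30).
#' @param total_steps scree length after flat extrapolation (default 100).
#' @return A list of class `stepwise_result`: `ordered_genes`, `scree`
#'   (tibble `step`, `gene`, `var_explained` of length `total_steps`, with
#'   `gene = NA` on extrapolated steps), `elbow_index`, `seed_genes`,
#'   `computed_steps`.
#' @export
stepwise_select <- function(ggc, computed_steps = 30, total_steps = 100) {
  stopifnot(inherits(ggc, "ggc_matrix"))
  p <- length(ggc$gene_index)
  if (total_steps < computed_steps) {
    stop("total_steps must be >= computed_steps", call. = FALSE)
  }
  if (p <= computed_steps) {
    computed_steps <- p - 1
    warning("fewer candidate genes than requested steps; ",
            "computed_steps lowered to ", computed_steps, call. = FALSE)
    if (computed_steps < 1) stop("need at least 2 candidate genes",
                                 call. = FALSE)
  }
  Gc <- center_columns(ggc$values)
  X <- crossprod(Gc)
  active <- rep(TRUE, p)
  order_idx <- integer(computed_steps)
  V_k <- numeric(computed_steps)
  for (k in seq_len(computed_steps)) {
    V <- variance_from_crossprod(X)
    V[!active] <- -Inf
    j <- which.max(V)  # ties -> smallest index
    order_idx[k] <- j
    V_k[k] <- max(V[j], 0)
    if (X[j, j] > 1e-12) {
      X <- X - tcrossprod(X[j, ]) / X[j, j]
    }
    active[j] <- FALSE
  }
  scree_vals <- c(V_k, rep(V_k[computed_steps], total_steps - computed_steps))
  elbow <- as.integer(min(elbow_point(scree_vals), computed_steps))
  ordered <- ggc$gene_index[order_idx]
  scree <- tibble::tibble(
    step = seq_len(total_steps),
    gene = c(ordered, rep(NA_character_, total_steps - computed_steps)),
    var_explained = scree_vals
  )
  structure(
    list(ordered_genes = ordered, scree = scree, elbow_index = elbow,
         seed_genes = ordered[seq_len(elbow)], computed_steps = computed_steps),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf(
    "<stepwise_result> %d computed steps, elbow at %d -> %d seed genes\n",
    x$computed_steps, x$elbow_index, length(x$seed_genes)))
  cat("  seeds:", paste(utils::head(x$seed_genes, 8), collapse = ", "),
      if (length(x$seed_genes) > 8) "...", "\n")
  invisible(x)
}
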