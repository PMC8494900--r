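#' Select feature genes for clustering a single-cell matrix
#'
#' Runs the full workflow: (optional) log-normalization, expression-fraction
#' and annotation gene filtering, gene-gene correlation scoring with the
#' binned correlation-range z-score, stepwise regression on the correlation
#' matrix to a minimally redundant seed set, guilt-by-association expansion
#' into a ranked feature ordering, and Density-Index optimization of the
#' feature-set size.
#'
#' @param mat an [expr_mat]; raw counts are log-normalized with
#'   `scale_factor` first, an already-normalized matrix is used as is.
#' @param min_cell_fraction detection-fraction gene filter (default 0.05).
#' @param exclusion_rules a [gene_exclusion_rules] for annotation filtering;
#'   `NULL` skips the annotation filter.
#' @param n_bins expression bins for the z-score (default 20; lowered
#'   automatically if the filtered gene count is small).
#' @param z_threshold candidate cutoff: keep genes with z-score strictly
#'   above this (default 0.7).
#' @param computed_steps real stepwise-regression steps (default 30).
#' @param total_steps scree length after flat extrapolation (default 100).
#' @param D principal components for the Density Index (default 20).
#' @param k nearest neighbors for the Density Index (default 10).
#' @param sizes feature-set size grid; `NULL` for [default_size_grid()],
#'   `FALSE` to skip size optimization and keep all ordered features.
#' @param scale_factor library-size target for log-normalization.
#' @param scale_features z-score features before PCA (default TRUE).
#' @param verbose print stage progress messages (default FALSE).
#' @return An object of class `feature_selection`; see [tidy.feature_selection()],
#'   [glance.feature_selection()], [autoplot.feature_selection()]. Key
#'   elements: `selected_features`, `gene_scores`, `stepwise`, `ordering`,
#'   `di_profile`, `config`.
#' @export
select_features <- function(mat,
                            min_cell_fraction = 0.05,
                            exclusion_rules = gene_exclusion_rules(
                              min_cell_fraction = min_cell_fraction),
                            n_bins = 20,
                            z_threshold = 0.7,
                            computed_steps = 30,
                            total_steps = 100,
                            D = 20,
                            k = 10,
                            sizes = NULL,
                            scale_factor = 1e4,
                            scale_features = TRUE,
                            verbose = FALSE) {
  stopifnot(inherits(mat, "expr_mat"))
  say <- function(...) if (verbose) message(...)

  if (!mat$normalized) {
    say("log-normalizing (scale factor ", format(scale_factor), ")")
    mat <- log_normalize(mat, scale_factor = scale_factor)
  }
  say("filtering genes detected in < ", format(100 * min_cell_fraction),
      "% of cells")
  mat <- filter_by_expression_fraction(mat, min_cell_fraction)
  if (!is.null(exclusion_rules)) {
    mat <- filter_by_annotation(mat, exclusion_rules, verbose = verbose)
  }
  # drop zero-variance genes (uncorrelatable; e.g. detected everywhere at
  # a constant value)
  vars <- row_variances(mat$values)
  if (any(vars == 0)) mat <- subset_features(mat, vars > 0)

  n_bins_eff <- max(1, min(n_bins, nrow(mat$values) %/% 2))
  if (n_bins_eff != n_bins) {
    say("reducing n_bins to ", n_bins_eff, " for ", nrow(mat$values),
        " genes")
  }
  say("scoring gene-gene correlations over ", nrow(mat$values), " genes")
  scores <- score_gene_correlations(mat, n_bins = n_bins_eff,
                                    z_threshold = z_threshold)
  ggc <- attr(scores, "ggc")
  cand <- scores$gene[scores$candidate]
  say(length(cand), " candidate genes with z > ", z_threshold)
  cand_idx <- match(cand, ggc$gene_index)
  ggc_cand <- structure(
    list(values = ggc$values[cand_idx, cand_idx, drop = FALSE],
         gene_index = cand),
    class = "ggc_matrix")

  sw <- stepwise_select(ggc_cand, computed_steps = computed_steps,
                        total_steps = total_steps)
  say(length(sw$seed_genes), " seed genes (elbow at step ", sw$elbow_index,
      ")")
  ordering <- expand_by_association(ggc_cand, sw$seed_genes)

  if (isFALSE(sizes)) {
    di <- NULL
    selected <- ordering$ordering$gene
  } else {
    n_ord <- nrow(ordering$ordering)
    n_seed <- length(sw$seed_genes)
    if (!is.null(sizes)) {
      # clamp a user grid to the feasible range [seed size, ordering length]
      sizes <- sort(unique(pmin(pmax(as.integer(sizes), n_seed), n_ord)))
      if (length(sizes) == 0) sizes <- n_ord
    }
    di <- optimize_feature_size(mat, ordering, sizes = sizes, D = D, k = k,
                                scale_features = scale_features)
    selected <- ordering$ordering$gene[seq_len(di$optimal_size)]
    say("DI optimum at ", di$optimal_size, " features")
  }

  structure(
    list(selected_features = selected,
         gene_scores = scores,
         stepwise = sw,
         ordering = ordering,
         di_profile = di,
         n_genes_in = length(scores$gene),
         config = list(min_cell_fraction = min_cell_fraction,
                       n_bins = n_bins_eff, z_threshold = z_threshold,
                       computed_steps = computed_steps,
                       total_steps = total_steps, D = D, k = k,
                       scale_factor = scale_factor,
                       scale_features = scale_features)),
    class = "feature_selection"
  )
}

row_variances <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(
    "<feature_selection> %d features selected (%d seeds, %d candidates, %d genes scored)\n",
    length(x$selected_features), length(x$stepwise$seed_genes),
    sum(x$gene_scores$candidate), x$n_genes_in))
  if (!is.null(x$di_profile)) {
    cat(sprintf("  DI-optimal size: %d (DI = %.3f)\n",
                x$di_profile$optimal_size, max(x$di_profile$profile$di)))
  }
  invisible(x)
}

#' Tidy a feature selection
#'
#' One row per ordered feature with its rank, seed flag, the association
#' score that admitted it and whether it falls inside the DI-optimal
#' feature set.
#'
#' @param x a `feature_selection`.
#' @param ... unused.
#' @return A tibble with columns `rank`, `gene`, `is_seed`,
#'   `association_score`, `selected`, `zscore`.
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  z <- stats::setNames(x$gene_scores$zscore, x$gene_scores$gene)
  dplyr::mutate(
    x$ordering$ordering,
    selected = .data$gene %in% x$selected_features,
    zscore = unname(z[.data$gene])
  )
}

#' One-row summary of a feature selection
#'
#' @param x a `feature_selection`.
#' @param ... unused.
#' @return A one-row tibble: `n_genes_scored`, `n_candidates`, `n_seeds`,
#'   `elbow_index`, `optimal_size`, `max_di`, `n_selected`.
#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(
    n_genes_scored = x$n_genes_in,
    n_candidates = sum(x$gene_scores$candidate),
    n_seeds = length(x$stepwise$seed_genes),
    elbow_index = x$stepwise$elbow_index,
    optimal_size = if (is.null(x$di_profile)) NA_integer_
                   else x$di_profile$optimal_size,
    max_di = if (is.null(x$di_profile)) NA_real_
             else max(x$di_profile$profile$di),
    n_selected = length(x$selected_features)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a feature selection
#'
#' `type = "di"` draws the Density-Index profile over feature-set size with
#' the optimum marked; `type = "scree"` draws the stepwise-regression scree
#' with the elbow marked; `type = "zscore"` shows the correlation-range
#' z-score against mean expression, colored by candidate status.
#'
#' @param object a `feature_selection`.
#' @param type one of `"di"`, `"scree"`, `"zscore"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot feature_selection
#' @export
autoplot.feature_selection <- function(object, type = c("di", "scree",
                                                        "zscore"), ...) {
  type <- match.arg(type)
  if (type == "di") {
    if (is.null(object$di_profile)) {
      stop("no DI profile in this fit (sizes = FALSE)", call. = FALSE)
    }
    plot_di_profile(object$di_profile)
  } else if (type == "scree") {
    plot_scree(object$stepwise)
  } else {
    ggplot2::ggplot(object$gene_scores,
                    ggplot2::aes(x = .data$mean_expr, y = .data$zscore,
                                 color = .data$candidate)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.7) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "mean normalized expression",
                    y = "correlation-range z-score", color = "candidate") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Density-Index profile
#'
#' @param x a `di_profile`.
#' @return A ggplot object.
#' @export
plot_di_profile <- function(x) {
  stopifnot(inherits(x, "di_profile"))
  ggplot2::ggplot(x$profile, ggplot2::aes(x = .data$size, y = .data$di)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$optimal_size, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "feature-set size", y = "Density Index") +
    ggplot2::theme_minimal()
}

#' Plot a stepwise-regression scree
#'
#' @param x a `stepwise_result`.
#' @return A ggplot object.
#' @export
plot_scree <- function(x) {
  stopifnot(inherits(x, "stepwise_result"))
  ggplot2::ggplot(x$scree,
                  ggplot2::aes(x = .data$step, y = .data$var_explained)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = x$elbow_index, linetype = "dashed") +
    ggplot2::labs(x = "regression step", y = "variance explained") +
    ggplot2::theme_minimal()
}
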