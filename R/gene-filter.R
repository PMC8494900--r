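#' Gene exclusion rules
#'
#' Bundles the two annotation-based exclusion mechanisms: case-insensitive
#' regular expressions matched against feature symbols (mitochondrial,
#' ribosomal and spike-in genes are recognizable from symbols alone) and an
#' explicit id list for classes, such as pseudogenes, whose status cannot be
#' inferred from the symbol.
#'
#' @param min_cell_fraction minimum fraction of cells in which a gene must be
#'   detected, in `[0, 1]`.
#' @param symbol_patterns character vector of regular expressions (matched
#'   case-insensitively against feature symbols).
#' @param explicit_ids optional character vector of feature ids to drop.
#' @return A list of class `gene_exclusion_rules`.
#' @seealso [default_exclusion_patterns()]
#' @export
gene_exclusion_rules <- function(min_cell_fraction = 0.05,
                                 symbol_patterns = default_exclusion_patterns(),
                                 explicit_ids = character()) {
  if (!is.numeric(min_cell_fraction) || length(min_cell_fraction) != 1 ||
      min_cell_fraction < 0 || min_cell_fraction > 1) {
    stop("min_cell_fraction must be a single number in [0, 1]", call. = FALSE)
  }
  for (p in symbol_patterns) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "x")); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid regular expression: ", p, call. = FALSE)
  }
  structure(list(min_cell_fraction = min_cell_fraction,
                 symbol_patterns = as.character(symbol_patterns),
                 explicit_ids = as.character(explicit_ids)),
            class = "gene_exclusion_rules")
}

#' Default symbol patterns for mitochondrial, ribosomal and spike-in genes
#'
#' Human/mouse/rat symbol conventions: `MT-`/`mt-` prefixes for mitochondrial
#' genes, `RPS`/`RPL` (`Rps`/`Rpl`) for ribosomal proteins, `ERCC-` for
#' spike-ins. Matching is case-insensitive, so one pattern per class covers
#' all three species.
#'
#' @param species one of `"human"`, `"mouse"`, `"rat"`; the pattern set is
#'   shared, the argument exists for interface stability.
#' @return Named character vector of regular expressions.
#' @export
default_exclusion_patterns <- function(species = c("human", "mouse", "rat")) {
  match.arg(species)
  c(mitochondrial = "^MT-", ribosomal = "^RP[SL]", spike_in = "^ERCC-")
}

#' Filter genes by detection fraction
#'
#' Retains genes detected (value > 0) in at least `min_cell_fraction` of
#' cells; the boundary is inclusive. Cells are never dropped.
#'
#' @param mat an [expr_mat].
#' @param min_cell_fraction fraction in `[0, 1]`, default 0.05.
#' @return The filtered [expr_mat].
#' @export
filter_by_expression_fraction <- function(mat, min_cell_fraction = 0.05) {
  stopifnot(inherits(mat, "expr_mat"))
  if (min_cell_fraction < 0 || min_cell_fraction > 1) {
    stop("min_cell_fraction must be in [0, 1]", call. = FALSE)
  }
  n_cells <- ncol(mat$values)
  frac <- Matrix::rowSums(mat$values > 0) / n_cells
  keep <- frac >= min_cell_fraction
  if (!any(keep)) {
    stop("no genes are detected in at least ",
         format(100 * min_cell_fraction), "% of cells; ",
         "lower min_cell_fraction", call. = FALSE)
  }
  subset_features(mat, features = keep)
}

#' Filter genes by annotation class
#'
#' Removes genes whose symbol matches any exclusion pattern
#' (case-insensitive) or whose id is explicitly listed. Empty rules are a
#' no-op. A message reports the number removed per category.
#'
#' @param mat an [expr_mat].
#' @param rules a [gene_exclusion_rules] object (only `symbol_patterns` and
#'   `explicit_ids` are consulted here).
#' @param verbose emit a per-category removal message (default TRUE).
#' @return The filtered [expr_mat].
#' @export
filter_by_annotation <- function(mat, rules = gene_exclusion_rules(),
                                 verbose = TRUE) {
  stopifnot(inherits(mat, "expr_mat"), inherits(rules, "gene_exclusion_rules"))
  drop <- rep(FALSE, nrow(mat$values))
  counts <- c()
  pats <- rules$symbol_patterns
  names(pats) <- if (is.null(names(pats))) pats else names(pats)
  for (nm in names(pats)) {
    hit <- grepl(pats[[nm]], mat$feature_symbols, ignore.case = TRUE)
    counts[nm] <- sum(hit & !drop)
    drop <- drop | hit
  }
  if (length(rules$explicit_ids)) {
    hit <- mat$feature_ids %in% rules$explicit_ids
    counts["explicit_ids"] <- sum(hit & !drop)
    drop <- drop | hit
  }
  if (verbose && length(counts) && sum(counts) > 0) {
    message("filter_by_annotation removed ",
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", "))
  }
  if (all(drop)) {
    stop("annotation filter removed every gene", call. = FALSE)
  }
  subset_features(mat, features = !drop)
}
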