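#' Run the feature-selection pipeline from a config and write artifacts
#'
#' File-to-file wrapper around [read_counts()] and [select_features()] used
#' by the command-line script. Writes into `outdir`:
#' `features.tsv` (rank, gene, is_seed, association_score, selected),
#' `di_profile.tsv` (size, di), `scree.tsv` (step, gene, var_explained),
#' `gene_scores.tsv`, `config.dcf` (the effective configuration) and
#' `run.log`.
#'
#' @param input path to the count matrix.
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param outdir output directory (created if needed).
#' @param ... passed to [select_features()] (e.g. `min_cell_fraction`,
#'   `n_bins`, `z_threshold`, `computed_steps`, `D`, `k`, `sizes`).
#' @param verbose print progress (default TRUE).
#' @return The `feature_selection` object, invisibly.
#' @export
run_pipeline <- function(input, format = c("mtx_dir", "csv", "tsv"),
                         outdir, ..., verbose = TRUE) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = log_path, append = TRUE)
    if (verbose) message(...)
  }
  log_line("reading ", input, " (", format, ")")
  mat <- read_counts(input, format = format)
  log_line(nrow(mat$values), " features x ", ncol(mat$values), " cells")
  fit <- select_features(mat, ..., verbose = verbose)
  log_line(length(fit$selected_features), " features selected")

  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(tidy(fit), "features.tsv")
  if (!is.null(fit$di_profile)) tsv(fit$di_profile$profile, "di_profile.tsv")
  tsv(fit$stepwise$scree, "scree.tsv")
  tsv(fit$gene_scores, "gene_scores.tsv")
  cfg <- c(list(input = input, format = format, outdir = outdir), fit$config)
  write.dcf(data.frame(lapply(cfg, as.character), check.names = FALSE),
            file.path(outdir, "config.dcf"))
  log_line("artifacts written to ", outdir)
  invisible(fit)
}
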