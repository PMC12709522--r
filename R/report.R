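# Distribution summaries, plotting, and run-configuration serialization.
# Smoothing is presentation-only; classification always uses the raw
# per-read percentages.

#' Summarize a per-read methylation percentage distribution
#'
#' Bins percents into `n_bins` equal bins over \[0,1\]; every bin is
#' left-closed and the final bin is right-inclusive. Fractions sum to 1.
#'
#' @param percents numeric vector of per-read methylation percents in \[0,1\].
#' @param n_bins number of bins (default 10).
#' @param assay_name,sample_id identifiers carried into the summary.
#' @return A `methyl_distribution`: `bin_edges` (length `n_bins + 1`),
#'   `bin_fractions`, `n_reads`.
#' @export
summarize_distribution <- function(percents, n_bins = 10L,
                                   assay_name = NA_character_,
                                   sample_id = NA_character_) {
  if (length(percents) == 0L) stop_config("no percents to summarize")
  if (n_bins < 2L) stop_config("n_bins must be >= 2")
  if (any(percents < 0 | percents > 1)) stop_config("percents outside [0,1]")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(percents, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(assay_name = assay_name, sample_id = sample_id,
                 bin_edges = edges, bin_fractions = counts / length(percents),
                 n_reads = length(percents)),
            class = "methyl_distribution")
}

#' @export
print.methyl_distribution <- function(x, ...) {
  cat(sprintf("methylation distribution (%s / %s), %d reads:\n",
              x$assay_name, x$sample_id, x$n_reads))
  lab <- sprintf("[%.2f,%.2f%s", head(x$bin_edges, -1), x$bin_edges[-1],
                 c(rep(")", length(x$bin_fractions) - 1L), "]"))
  cat(paste(sprintf("  %-12s %.3f", lab, x$bin_fractions), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
plot.methyl_distribution <- function(x, ...,
                                     main = NULL, col = "steelblue") {
  main <- main %||% sprintf("%s / %s (n = %d reads)", x$assay_name,
                            x$sample_id, x$n_reads)
  mids <- (head(x$bin_edges, -1) + x$bin_edges[-1]) / 2
  barplot(x$bin_fractions, names.arg = sprintf("%.1f", mids),
          xlab = "methylation fraction per read", ylab = "fraction of reads",
          main = main, col = col, border = NA, ...)
  invisible(x)
}

#' Serialize the effective configuration of a run
#'
#' Writes the configuration (parameters, seeds, paths) as YAML so every
#' artifact can be reproduced from the file sitting next to it.
#'
#' @param config named list of parameters.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("methylmark"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a per-assay diagnostic report as TSV
#'
#' @param report data.frame from [assay_report()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assay_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
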