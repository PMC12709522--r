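# Candidate diagnostic region selection and ranking.
#
# A candidate region is a maximal run of qualifying CpGs (informativeness
# above the floor) whose first-to-last span is at most max_span_bp and which
# holds at least min_cpg sites. Overlapping candidates are resolved greedily
# by region score. The region score averages the best top_fraction of member
# informativeness values and adds a log2 CpG-count bonus.

# Region score on a vector of member informativeness values.
region_score_value <- function(scores, config) {
  n <- length(scores)
  m <- ceiling(config$top_fraction * n)
  top <- sort(scores, decreasing = TRUE)[seq_len(m)]
  mean(top) + config$cpg_count_bonus * log2(n / config$min_cpg)
}

# Majority region type over member CpGs; per-CpG ties and the overall tie go
# to hypo.
region_type_majority <- function(hypo, hyper) {
  votes_hypo <- sum(hypo >= hyper)
  if (votes_hypo >= length(hypo) - votes_hypo) "hypo" else "hyper"
}

#' Find candidate diagnostic regions
#'
#' Scans a sorted per-position score table for maximal runs of qualifying
#' CpGs (informativeness strictly above `config$score_floor`) with
#' first-to-last distance at most `config$max_span_bp` and at least
#' `config$min_cpg` members. Overlapping candidates (sharing a member CpG)
#' are resolved by keeping the higher region score, ties by more CpGs, then
#' by leftmost coordinate. Region coordinates are 0-based half-open over the
#' first-to-last member cytosine.
#'
#' @param scores data.frame from [score_compendium()], sorted by
#'   (chrom, pos).
#' @param config a [scoring_config()].
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `region_type`, `n_cpg`, `region_score` and list columns
#'   `cpg_positions`, `cpg_scores`.
#' @export
find_candidate_regions <- function(scores, config = scoring_config()) {
  ord <- order(scores$chrom, scores$pos)
  if (!identical(ord, seq_len(nrow(scores))))
    stop_config("scores must be sorted by (chrom, pos)")
  out <- list()
  for (chr in unique(scores$chrom)) {
    s <- scores[scores$chrom == chr, , drop = FALSE]
    q <- s[s$informativeness > config$score_floor, , drop = FALSE]
    m <- nrow(q)
    if (m < config$min_cpg) next
    pos <- q$pos
    # j_of[i]: furthest index j with pos[j] - pos[i] <= max_span_bp
    j_of <- vapply(seq_len(m), function(i)
      max(which(pos - pos[i] <= config$max_span_bp)), integer(1))
    for (i in seq_len(m)) {
      j <- j_of[i]
      # maximal: cannot extend left (previous start reaches no further)
      if (i > 1L && j_of[i - 1L] == j) next
      if (j - i + 1L < config$min_cpg) next
      idx <- i:j
      out[[length(out) + 1L]] <- list(
        chrom = chr, idx_start = i, idx_end = j,
        start = pos[i], end = pos[j] + 1,
        n_cpg = length(idx),
        region_type = region_type_majority(q$hypo_score[idx], q$hyper_score[idx]),
        region_score = region_score_value(q$informativeness[idx], config),
        cpg_positions = pos[idx],
        cpg_scores = q$informativeness[idx])
    }
  }
  if (length(out) == 0L) return(empty_region_frame())
  df <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    region_type = vapply(out, `[[`, "", "region_type"),
    n_cpg = vapply(out, function(r) r$n_cpg, integer(1)),
    region_score = vapply(out, `[[`, 0, "region_score"),
    stringsAsFactors = FALSE)
  df$cpg_positions <- lapply(out, `[[`, "cpg_positions")
  df$cpg_scores <- lapply(out, `[[`, "cpg_scores")

  # Greedy overlap resolution: best score, then more CpGs, then leftmost.
  o <- order(-df$region_score, -df$n_cpg, df$chrom, df$start)
  kept <- logical(nrow(df))
  for (i in o) {
    ov <- kept & df$chrom == df$chrom[i] &
      df$start < df$end[i] & df$end > df$start[i]
    if (!any(ov)) kept[i] <- TRUE
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_region_frame <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   region_type = character(), n_cpg = integer(),
                   region_score = numeric(), stringsAsFactors = FALSE)
  df$cpg_positions <- list()
  df$cpg_scores <- list()
  df
}

#' Rank candidate regions
#'
#' Recomputes each region's score (mean of the top `top_fraction` member
#' informativeness values plus `cpg_count_bonus * log2(n_cpg / min_cpg)`) and
#' sorts descending; ties broken by CpG count, then coordinate. Adds a `rank`
#' column.
#'
#' @param regions data.frame from [find_candidate_regions()].
#' @param config a [scoring_config()].
#' @return The regions sorted by rank with columns `rank` and `region_score`
#'   updated.
#' @export
rank_regions <- function(regions, config = scoring_config()) {
  if (nrow(regions) == 0L) {
    regions$rank <- integer()
    return(regions)
  }
  regions$region_score <- vapply(regions$cpg_scores, region_score_value, 0,
                                 config = config)
  o <- order(-regions$region_score, -regions$n_cpg, regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  regions
}

#' Export candidate regions as BED6
#'
#' Name is the region rank, the BED score column is the region score mapped
#' to 0-1000 via `round(1000 * exp(region_score))` (score 0 -> 1000), strand
#' is ".".
#'
#' @param regions ranked regions from [rank_regions()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  rank <- regions$rank %||% seq_len(nrow(regions))
  bed_score <- pmax(0, pmin(1000, round(1000 * exp(regions$region_score))))
  lines <- sprintf("%s\t%d\t%d\tregion_%d\t%d\t.",
                   regions$chrom, as.integer(regions$start),
                   as.integer(regions$end), rank, as.integer(bed_score))
  writeLines(lines, path)
  invisible(path)
}

#' Export candidate region sequences as FASTA
#'
#' Convenience for downstream cross-species screening with external tools.
#' Requires the chromosome sequences.
#'
#' @param regions ranked regions from [rank_regions()].
#' @param genome a named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences; coordinates are 0-based half-open.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1,
                                    end = regions$end[i]))
  }, ""))
  names(seqs) <- sprintf("region_%d %s:%d-%d",
                         regions$rank %||% seq_len(nrow(regions)),
                         regions$chrom, as.integer(regions$start),
                         as.integer(regions$end))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
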