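# Shared fixtures and independent oracles, built in code at test time.

# Small hand-designed assay: 8-bp CpG-free primer regions, 3 interior CpGs.
tiny_assay <- function() {
  ref <- paste0("AATTAGGT", "ACGTTACGATTTCGAA", "TTAGGATT")
  amplicon_assay(name = "tiny", region_type = "hypo", chrom = "chrT",
                 start = 100, end = 100 + nchar(ref),
                 forward_primer = chartr("C", "T", substr(ref, 1, 8)),
                 reverse_primer = revcomp_str(chartr("C", "T",
                   substr(ref, nchar(ref) - 7, nchar(ref)))),
                 reference_seq = ref)
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hand-build a bisulfite read for an assay: converted reference with each CpG
# cytosine set per `states` (TRUE = methylated = C). Independent of the
# package's generator.
build_read <- function(assay, states) {
  x <- strsplit(assay$reference_seq, "")[[1]]
  is_c <- x == "C"
  x[is_c] <- "T"
  x[assay$cpg_offsets] <- ifelse(states, "C", "T")
  # primer regions are synthesized, not converted template
  lf <- nchar(assay$forward_primer)
  x[seq_len(lf)] <- strsplit(assay$forward_primer, "")[[1]]
  lr <- nchar(assay$reverse_primer)
  L <- length(x)
  x[(L - lr + 1):L] <- strsplit(revcomp_str(assay$reverse_primer), "")[[1]]
  paste(x, collapse = "")
}

# Split a full-length molecule into a 150-bp R1/R2 pair.
split_pair <- function(molecule, read_length = 150L) {
  L <- nchar(molecule)
  list(r1 = substr(molecule, 1, min(read_length, L)),
       r2 = revcomp_str(substr(molecule, max(1, L - read_length + 1), L)))
}

# Write sequences as a FASTQ file (constant quality).
write_test_fastq <- function(seqs, path, qual_char = "D") {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(path)
  }
  ids <- sprintf("read%05d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep(qual_char, nchar(seqs)))), path)
  path
}

# Exhaustive window-enumeration oracle for candidate region finding:
# all index windows with enough CpGs and allowed span, kept if no strict
# superset window also satisfies the span, then greedy selection by
# (score, n_cpg, leftmost). Plain loops, independent of the implementation.
region_oracle <- function(scores, config = scoring_config()) {
  all_windows <- list()
  for (chr in unique(scores$chrom)) {
    s <- scores[scores$chrom == chr, , drop = FALSE]
    q <- s[s$informativeness > config$score_floor, , drop = FALSE]
    m <- nrow(q)
    if (m < config$min_cpg) next
    pos <- q$pos
    wins <- list()
    for (i in seq_len(m)) for (j in i:m) {
      if (pos[j] - pos[i] > config$max_span_bp) break
      if (j - i + 1 >= config$min_cpg)
        wins[[length(wins) + 1]] <- c(i, j)
    }
    if (!length(wins)) next
    spans_ok <- function(i, j) pos[j] - pos[i] <= config$max_span_bp
    for (w in wins) {
      i <- w[1]; j <- w[2]
      maximal <- TRUE
      if (i > 1 && spans_ok(i - 1, j)) maximal <- FALSE
      if (j < m && spans_ok(i, j + 1)) maximal <- FALSE
      if (!maximal) next
      idx <- i:j
      vals <- q$informativeness[idx]
      n <- length(idx)
      top <- sort(vals, decreasing = TRUE)[seq_len(ceiling(config$top_fraction * n))]
      sc <- mean(top) + config$cpg_count_bonus * log2(n / config$min_cpg)
      votes_hypo <- sum(q$hypo_score[idx] >= q$hyper_score[idx])
      ty <- if (votes_hypo >= n - votes_hypo) "hypo" else "hyper"
      all_windows[[length(all_windows) + 1]] <- data.frame(
        chrom = chr, start = as.numeric(pos[i]), end = as.numeric(pos[j] + 1),
        region_type = ty, n_cpg = as.integer(n), region_score = sc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(all_windows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), region_type = character(),
                      n_cpg = integer(), region_score = numeric()))
  df <- do.call(rbind, all_windows)
  o <- order(-df$region_score, -df$n_cpg, df$chrom, df$start)
  kept <- logical(nrow(df))
  for (i in o) {
    overlaps <- kept & df$chrom == df$chrom[i] &
      df$start < df$end[i] & df$end > df$start[i]
    if (!any(overlaps)) kept[i] <- TRUE
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random per-position score table for oracle comparisons.
random_score_table <- function(n_cpg, frac_qualifying = 0.4) {
  pos <- sort(sample.int(3000, n_cpg))
  inf <- ifelse(runif(n_cpg) < frac_qualifying,
                runif(n_cpg, -1.9, 0), runif(n_cpg, -8, -2.1))
  hypo <- inf - ifelse(runif(n_cpg) < 0.5, 0, runif(n_cpg, 0, 3))
  hyper <- ifelse(hypo < inf, inf, inf - runif(n_cpg, 0, 3))
  data.frame(chrom = "chrR", pos = pos, hypo_score = pmin(hypo, 0),
             hyper_score = pmin(hyper, 0),
             informativeness = pmax(pmin(hypo, 0), pmin(hyper, 0)),
             stringsAsFactors = FALSE)
}

# Default per-read percent pools for an assay archetype, drawn at the
# molecule level (the detection resampler consumes percents).
default_pools <- function(assay, n = 10000L, seed = 1L) {
  set.seed(seed)
  brain <- rowMeans(sample_molecule(brain_profile(assay), n)$patterns)
  decoy <- rowMeans(sample_molecule(decoy_profile(assay), n)$patterns)
  list(brain = brain, decoy = decoy)
}
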