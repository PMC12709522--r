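# Per-read validation and methylation-pattern calling for targeted bisulfite
# amplicons. Filters are applied in a fixed order so every read carries
# exactly one rejection reason: forward primer match -> pair merge / CpG
# coverage -> alignment identity -> CpG dinucleotide state.

REJECTION_REASONS <- c("primer_mismatch", "unmergeable_pair",
                       "incomplete_cpg_coverage", "low_identity",
                       "invalid_cpg_state")

#' Read-caller configuration
#'
#' @param min_identity alignment identity a read must exceed (strict `>`,
#'   default 0.85); CpG cytosine columns are excluded from the identity.
#' @param min_valid_reads a sample with fewer valid reads is discarded
#'   (default 100).
#' @param merge_min_overlap minimum read-pair overlap in bp (default 20).
#' @param merge_min_agreement minimum base agreement over the overlap
#'   (default 0.9).
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend global
#'   alignment scores (defaults +1/-1/-2/-1; gap penalties are passed to the
#'   aligner as costs `gapOpening = 2`, `gapExtension = 1`).
#' @param strict_literal_ct if `TRUE`, a CpG dinucleotide on the read must
#'   read CG (methylated) or CT (unmethylated) literally; the default `FALSE`
#'   uses the chemistry-consistent CG/TG (a bisulfite-converted unmethylated
#'   CpG reads TG on the top strand).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_identity = 0.85, min_valid_reads = 100L,
                          merge_min_overlap = 20L, merge_min_agreement = 0.9,
                          align_match = 1L, align_mismatch = -1L,
                          align_gap_open = -2L, align_gap_extend = -1L,
                          strict_literal_ct = FALSE) {
  stopifnot(min_identity > 0, min_identity < 1, min_valid_reads >= 0,
            merge_min_overlap >= 1, merge_min_agreement > 0,
            merge_min_agreement <= 1)
  structure(list(min_identity = min_identity,
                 min_valid_reads = as.integer(min_valid_reads),
                 merge_min_overlap = as.integer(merge_min_overlap),
                 merge_min_agreement = merge_min_agreement,
                 align_match = align_match, align_mismatch = align_mismatch,
                 align_gap_open = align_gap_open,
                 align_gap_extend = align_gap_extend,
                 strict_literal_ct = isTRUE(strict_literal_ct)),
            class = "caller_config")
}

# Substitution matrix for read-vs-converted-reference alignment: the CpG
# wildcard Y scores as a match against C or T.
caller_substitution_matrix <- function(config) {
  m <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$align_match, mismatch = config$align_mismatch,
    baseOnly = FALSE)
  m["Y", "C"] <- m["C", "Y"] <- config$align_match
  m["Y", "T"] <- m["T", "Y"] <- config$align_match
  m
}

#' Merge a read pair by ungapped overlap
#'
#' R2 is reverse-complemented and slid along R1; the merge uses the ungapped
#' overlap of at least `merge_min_overlap` bp with the highest base
#' agreement (ties prefer the longer overlap), provided the agreement reaches
#' `merge_min_agreement`. Disagreeing overlap bases are resolved by the
#' higher base quality, ties by the R1 base.
#'
#' @param r1,r2 read sequences; `r2` in sequencing orientation.
#' @param q1,q2 optional quality strings (Phred+33).
#' @param config a [caller_config()].
#' @param expected_shift optional offset of the reverse-complemented R2 within
#'   R1 to try first (e.g. reference length minus R2 length); accepted without
#'   a scan only when its overlap agrees perfectly (another shift could tie at
#'   perfect agreement only for repetitive sequence).
#' @return A list with `seq`, `qual`, `overlap`, `agreement`, or `NULL` when
#'   no qualifying overlap exists.
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL, config = caller_config(),
                       expected_shift = NULL) {
  b1 <- charToRaw(r1)
  b2 <- revcomp_raw(charToRaw(r2))
  n1 <- length(b1); n2 <- length(b2)
  qb1 <- if (!is.null(q1)) charToRaw(q1) else rep(as.raw(73L), n1)
  qb2 <- if (!is.null(q2)) rev(charToRaw(q2)) else rep(as.raw(73L), n2)
  best <- list(agree = -1, s = NA_integer_, o = NA_integer_)
  if (!is.null(expected_shift) && expected_shift >= 0 &&
      expected_shift <= n1 - config$merge_min_overlap) {
    s <- as.integer(expected_shift)
    o <- min(n1 - s, n2)
    if (o >= config$merge_min_overlap &&
        all(b1[(s + 1L):(s + o)] == b2[seq_len(o)]))
      best <- list(agree = 1, s = s, o = o)
  }
  if (best$agree < 1) {
    for (s in 0:(n1 - config$merge_min_overlap)) {
      o <- min(n1 - s, n2)
      if (o < config$merge_min_overlap) break
      agree <- sum(b1[(s + 1L):(s + o)] == b2[seq_len(o)]) / o
      if (agree > best$agree) best <- list(agree = agree, s = s, o = o)
    }
  }
  if (best$agree < config$merge_min_agreement) return(NULL)
  s <- best$s; o <- best$o
  ov1 <- b1[(s + 1L):(s + o)]; ov2 <- b2[seq_len(o)]
  qv1 <- qb1[(s + 1L):(s + o)]; qv2 <- qb2[seq_len(o)]
  take2 <- ov1 != ov2 & qv2 > qv1
  cons <- ov1; cons[take2] <- ov2[take2]
  qcons <- pmax(as.integer(qv1), as.integer(qv2))
  merged <- c(b1[seq_len(s)], cons, if (n2 > o) b2[(o + 1L):n2] else raw(0))
  mqual <- c(as.integer(qb1[seq_len(s)]), qcons,
             if (n2 > o) as.integer(qb2[(o + 1L):n2]) else integer(0))
  list(seq = rawToChar(merged), qual = rawToChar(as.raw(mqual)),
       overlap = o, agreement = best$agree)
}

# Precomputed per-assay context so per-read work stays cheap.
make_caller_context <- function(assay, config) {
  stopifnot(inherits(assay, "amplicon_assay"))
  if (is.null(assay$converted_ref))
    stop_config("assay %s has no converted reference", assay$name)
  cref <- assay$converted_ref
  refb <- charToRaw(cref)
  L <- length(refb)
  y_mask <- logical(L)
  y_mask[assay$cpg_offsets] <- TRUE
  primer <- assay$forward_primer
  list(assay = assay, config = config, cref = cref, refb = refb, L = L,
       y_mask = y_mask, non_y = !y_mask, n_non_y = sum(!y_mask),
       primer = primer, primer_n = nchar(primer),
       primer_exact = !grepl("[^ACGT]", primer),
       primer_allowed = lapply(chars(primer), function(p) IUPAC_CODES[[p]]),
       last_needed = if (length(assay$cpg_offsets))
         max(assay$cpg_offsets) + 1L else 0L,
       submat = caller_substitution_matrix(config),
       raw_C = charToRaw("C"), raw_T = charToRaw("T"), raw_G = charToRaw("G"))
}

# Identity and per-reference-position read bases. Substitution-only reads of
# reference length take an ungapped fast path; anything else goes through a
# global alignment (affine gaps, CpG-Y scored as C/T match). Identity is
# matches / (alignment columns - CpG cytosine columns).
align_to_ref <- function(ctx, read) {
  rb <- charToRaw(read)
  if (length(rb) == ctx$L) {
    eq <- rb == ctx$refb | (ctx$y_mask & (rb == ctx$raw_C | rb == ctx$raw_T))
    identity <- sum(eq & ctx$non_y) / ctx$n_non_y
    if (identity >= 0.95)
      return(list(identity = identity, read_at = rb, gapped = FALSE))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ctx$cref),
    type = "global", substitutionMatrix = ctx$submat,
    gapOpening = abs(ctx$config$align_gap_open),
    gapExtension = abs(ctx$config$align_gap_extend))
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))
  is_y_col <- s == "Y"
  match_col <- (p == s & p != "-") | (is_y_col & p %in% c("C", "T"))
  identity <- sum(match_col & !is_y_col) / (length(s) - sum(is_y_col))
  read_at <- rep(as.raw(45L), ctx$L)  # "-"
  refpos <- cumsum(s != "-")
  covered <- s != "-"
  read_at[refpos[covered]] <- charToRaw(paste(p[covered], collapse = ""))
  list(identity = identity, read_at = read_at, gapped = TRUE)
}

call_read_ctx <- function(ctx, r1, r2 = NULL, q1 = NULL, q2 = NULL,
                          read_id = "read") {
  config <- ctx$config
  assay <- ctx$assay
  fail <- function(reason, identity = NA_real_) {
    structure(list(read_id = read_id, assay_name = assay$name, states = NULL,
                   methylation_percent = NA_real_, identity = identity,
                   valid = FALSE, rejection_reason = reason),
              class = "read_call")
  }
  # 1. forward primer at read start, zero mismatches (IUPAC-aware)
  if (ctx$primer_exact) {
    if (substr(r1, 1L, ctx$primer_n) != ctx$primer) return(fail("primer_mismatch"))
  } else {
    if (nchar(r1) < ctx$primer_n) return(fail("primer_mismatch"))
    rb <- chars(substr(r1, 1L, ctx$primer_n))
    for (i in seq_len(ctx$primer_n))
      if (!(rb[i] %in% ctx$primer_allowed[[i]])) return(fail("primer_mismatch"))
  }
  # 2. pair merge, then CpG coverage of the merged fragment
  if (!is.null(r2)) {
    m <- merge_pair(r1, r2, q1, q2, config,
                    expected_shift = ctx$L - nchar(r2))
    if (is.null(m)) return(fail("unmergeable_pair"))
    merged <- m$seq
  } else {
    merged <- r1
  }
  if (nchar(merged) < ctx$last_needed) return(fail("incomplete_cpg_coverage"))
  # 3. alignment identity (strict >), CpG cytosine columns excluded
  ali <- align_to_ref(ctx, merged)
  if (!(ali$identity > config$min_identity))
    return(fail("low_identity", ali$identity))
  # 4. CpG dinucleotide states
  off <- assay$cpg_offsets
  b <- ali$read_at[off]
  g <- ali$read_at[off + 1L]
  if (config$strict_literal_ct) {
    ok <- b == ctx$raw_C & (g == ctx$raw_G | g == ctx$raw_T)
    meth <- g == ctx$raw_G
  } else {
    ok <- (b == ctx$raw_C | b == ctx$raw_T) & g == ctx$raw_G
    meth <- b == ctx$raw_C
  }
  if (!all(ok)) return(fail("invalid_cpg_state", ali$identity))
  structure(list(read_id = read_id, assay_name = assay$name,
                 states = as.logical(meth),
                 methylation_percent = mean(meth),
                 identity = ali$identity, valid = TRUE,
                 rejection_reason = "none"),
            class = "read_call")
}

#' Validate one read (or pair) against an assay and call its pattern
#'
#' Applies, in order: forward-primer match at the read start, pair merging
#' and CpG coverage, alignment identity (strict `>` `min_identity`, CpG
#' cytosines excluded), and per-CpG dinucleotide validity (CG = methylated,
#' TG = unmethylated by default). The first failing filter is recorded as the
#' read's single rejection reason.
#'
#' @param r1 read sequence (merged-read start = amplicon 5' end).
#' @param r2 optional mate, sequencing orientation.
#' @param assay an [amplicon_assay()] with a reference.
#' @param config a [caller_config()].
#' @param q1,q2 optional quality strings.
#' @param read_id identifier carried into the call.
#' @return A `read_call`: `states` (logical per CpG), `methylation_percent`,
#'   `identity`, `valid`, `rejection_reason`.
#' @export
call_read <- function(r1, r2 = NULL, assay, config = caller_config(),
                      q1 = NULL, q2 = NULL, read_id = "read") {
  ctx <- make_caller_context(assay, config)
  call_read_ctx(ctx, r1, r2, q1, q2, read_id)
}

#' Process a sample's FASTQ against one assay
#'
#' Runs [call_read()] over every read (pair), keeping per-read methylation
#' patterns and percentages for valid reads and a per-reason rejection
#' account. The sample is flagged discarded when it yields fewer than
#' `config$min_valid_reads` valid reads.
#'
#' @param fastq_r1 path to R1 FASTQ (optionally gzip).
#' @param fastq_r2 path to R2 FASTQ, or `NULL` for single-end use when reads
#'   span all CpGs.
#' @param assay an [amplicon_assay()] with a reference.
#' @param config a [caller_config()].
#' @param sample_id sample identifier.
#' @return A `sample_read_set`: `valid_calls` (data.frame `read_id`,
#'   `pattern`, `methylation_percent`, `identity`), `rejection_counts`,
#'   `n_total`, `discarded`.
#' @export
process_sample <- function(fastq_r1, fastq_r2 = NULL, assay,
                           config = caller_config(), sample_id = "sample") {
  reads1 <- Biostrings::readDNAStringSet(fastq_r1, format = "fastq",
                                         with.qualities = TRUE)
  s1 <- as.character(reads1)
  q1 <- as.character(S4Vectors::mcols(reads1)$qualities)
  ids <- sub("\\s.*$", "", names(reads1))
  s2 <- q2 <- NULL
  if (!is.null(fastq_r2)) {
    reads2 <- Biostrings::readDNAStringSet(fastq_r2, format = "fastq",
                                           with.qualities = TRUE)
    if (length(reads2) != length(reads1))
      stop_config("R1/R2 record counts differ (%d vs %d)",
                  length(reads1), length(reads2))
    s2 <- as.character(reads2)
    q2 <- as.character(S4Vectors::mcols(reads2)$qualities)
  }
  ctx <- make_caller_context(assay, config)
  n <- length(s1)
  rej <- setNames(integer(length(REJECTION_REASONS)), REJECTION_REASONS)
  keep_id <- keep_pat <- character(n)
  keep_pct <- keep_idy <- numeric(n)
  nv <- 0L
  for (i in seq_len(n)) {
    cl <- call_read_ctx(ctx, s1[i],
                        if (is.null(s2)) NULL else s2[i],
                        if (is.null(q1)) NULL else q1[i],
                        if (is.null(q2)) NULL else q2[i],
                        read_id = ids[i])
    if (cl$valid) {
      nv <- nv + 1L
      keep_id[nv] <- cl$read_id
      keep_pat[nv] <- paste(as.integer(cl$states), collapse = "")
      keep_pct[nv] <- cl$methylation_percent
      keep_idy[nv] <- cl$identity
    } else {
      rej[cl$rejection_reason] <- rej[cl$rejection_reason] + 1L
    }
  }
  keep_id <- keep_id[seq_len(nv)]; keep_pat <- keep_pat[seq_len(nv)]
  keep_pct <- keep_pct[seq_len(nv)]; keep_idy <- keep_idy[seq_len(nv)]
  structure(list(
    sample_id = sample_id, assay_name = assay$name,
    region_type = assay$region_type,
    valid_calls = data.frame(read_id = keep_id, pattern = keep_pat,
                             methylation_percent = keep_pct,
                             identity = keep_idy, stringsAsFactors = FALSE),
    rejection_counts = rej, n_total = n,
    discarded = length(keep_id) < config$min_valid_reads),
    class = "sample_read_set")
}

#' @export
print.sample_read_set <- function(x, ...) {
  cat(sprintf("sample %s / assay %s (%s): %d of %d reads valid%s\n",
              x$sample_id, x$assay_name, x$region_type,
              nrow(x$valid_calls), x$n_total,
              if (x$discarded) " [DISCARDED: < min valid reads]" else ""))
  rj <- x$rejection_counts[x$rejection_counts > 0]
  if (length(rj))
    cat(paste(sprintf("  %s: %d", names(rj), rj), collapse = "\n"), "\n")
  invisible(x)
}

#' Write per-read calls and a per-sample JSON summary
#'
#' @param read_set a `sample_read_set` from [process_sample()].
#' @param calls_path output TSV of valid calls.
#' @param summary_path optional output JSON with counts and the discard flag.
#' @return `calls_path`, invisibly.
#' @export
write_read_calls <- function(read_set, calls_path, summary_path = NULL) {
  write.table(read_set$valid_calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(
      sample_id = read_set$sample_id, assay_name = read_set$assay_name,
      region_type = read_set$region_type, n_total = read_set$n_total,
      n_valid = nrow(read_set$valid_calls),
      rejection_counts = as.list(read_set$rejection_counts),
      discarded = read_set$discarded),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(calls_path)
}
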