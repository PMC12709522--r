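# Targeted amplicon assays: primers with adapter overhangs, amplicon
# reference, in-silico bisulfite-converted reference, and CpG site offsets.

#' Enumerate CpG sites in a sequence
#'
#' Offsets (1-based) of every cytosine immediately followed by guanine.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return Integer vector of ascending offsets (empty when no CpG).
#' @export
enumerate_cpg_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Models full conversion of the top strand: every non-CpG cytosine becomes
#' T (unmethylated by the standard mammalian assumption), every CpG cytosine
#' becomes the wildcard Y (C or T depending on the molecule's methylation
#' state), all other bases are unchanged.
#'
#' @param seq nucleotide string over A/C/G/T.
#' @return Converted string of the same length.
#' @export
bisulfite_convert_reference <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGT]", seq)) stop_config("reference must be over A/C/G/T")
  x <- chars(seq)
  cpg <- enumerate_cpg_sites(seq)
  is_c <- x == "C"
  x[is_c] <- "T"
  x[cpg] <- "Y"
  paste(x, collapse = "")
}

#' Match a base against an IUPAC code
#'
#' @param read_base single character, the observed base.
#' @param code single IUPAC nucleotide code.
#' @return `TRUE` iff `read_base` is in the expansion of `code`.
#' @export
iupac_match <- function(read_base, code) {
  exp <- IUPAC_CODES[[toupper(code)]]
  if (is.null(exp)) stop_config("invalid IUPAC code: %s", code)
  toupper(read_base) %in% exp
}

#' Match a read prefix against a (possibly degenerate) primer
#'
#' Exact, zero-mismatch match of every primer position under IUPAC expansion.
#'
#' @param read_prefix string at least as long as `primer`.
#' @param primer IUPAC nucleotide string (genome-specific part, no overhang).
#' @return `TRUE` iff the primer matches the start of `read_prefix` exactly.
#' @export
match_primer <- function(read_prefix, primer) {
  np <- nchar(primer)
  if (nchar(read_prefix) < np) return(FALSE)
  pb <- chars(primer)
  rb <- chars(substr(read_prefix, 1L, np))
  for (i in seq_len(np)) {
    exp <- IUPAC_CODES[[pb[i]]]
    if (is.null(exp)) stop_config("invalid IUPAC code in primer: %s", pb[i])
    if (!(rb[i] %in% exp)) return(FALSE)
  }
  TRUE
}

#' Construct an amplicon assay
#'
#' Represents one targeted bisulfite amplicon: genome-specific primers (IUPAC
#' allowed), optional adapter overhangs, genomic coordinates (0-based
#' half-open), the expected direction of the brain contrast (`hypo`/`hyper`),
#' and optionally the untreated amplicon reference from which the
#' bisulfite-converted reference and CpG offsets are derived.
#'
#' @param name assay name.
#' @param region_type `"hypo"` or `"hyper"`.
#' @param chrom,start,end genomic coordinates, 0-based half-open.
#' @param forward_primer,reverse_primer genome-specific primer strings.
#' @param forward_overhang,reverse_overhang adapter tails (stored, never
#'   matched against inserts).
#' @param reference_seq untreated amplicon sequence (optional for
#'   discovery-only use; required for read calling and simulation).
#' @return An `amplicon_assay` list with `converted_ref` (top strand with CpG
#'   cytosines as Y) and `cpg_offsets` (1-based, ascending) when
#'   `reference_seq` is supplied.
#' @export
amplicon_assay <- function(name, region_type = c("hypo", "hyper"), chrom,
                           start, end, forward_primer, reverse_primer,
                           forward_overhang = "", reverse_overhang = "",
                           reference_seq = NULL) {
  region_type <- match.arg(region_type)
  if (start >= end) stop_config("assay %s: start >= end", name)
  a <- list(name = name, region_type = region_type, chrom = chrom,
            start = start, end = end, length_bp = end - start,
            forward_primer = toupper(forward_primer),
            reverse_primer = toupper(reverse_primer),
            forward_overhang = forward_overhang,
            reverse_overhang = reverse_overhang,
            reference_seq = NULL, converted_ref = NULL,
            cpg_offsets = integer(0))
  if (!is.null(reference_seq)) {
    reference_seq <- toupper(reference_seq)
    a$reference_seq <- reference_seq
    a$converted_ref <- bisulfite_convert_reference(reference_seq)
    a$cpg_offsets <- enumerate_cpg_sites(reference_seq)
    if (nchar(reference_seq) != a$length_bp)
      warning(sprintf("assay %s: reference length %d differs from end - start = %d",
                      name, nchar(reference_seq), a$length_bp))
  }
  structure(a, class = "amplicon_assay")
}

#' @export
print.amplicon_assay <- function(x, ...) {
  cat(sprintf("amplicon assay %s [%s] %s:%d-%d (%d bp)\n", x$name,
              x$region_type, x$chrom, x$start, x$end, x$length_bp))
  if (!is.null(x$reference_seq))
    cat(sprintf("  %d CpG sites; converted reference attached\n",
                length(x$cpg_offsets)))
  invisible(x)
}

#' Load an assay definition table
#'
#' Parses a TSV with header columns `name`, `forward_primer`,
#' `reverse_primer`, `type`, `chrom`, `start`, `end` and optionally
#' `reference_fasta`. Adapter overhangs are written in parentheses ahead of
#' the genome-specific primer, e.g. `"(ACGT...)TATTAT..."`; a primer without
#' parseable parentheses yields a format warning and is treated as having no
#' overhang. Coordinates may contain thousands separators. Rows whose
#' coordinate span disagrees with an attached reference length are flagged
#' with a validation warning (see [amplicon_assay()]).
#'
#' @param path assay table path.
#' @param reference_fasta optional FASTA of amplicon reference sequences,
#'   matched to assays by record name; overrides any `reference_fasta` column.
#' @return A list of [amplicon_assay()] objects, named by assay.
#' @export
load_assay_table <- function(path, reference_fasta = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "")
  if (nrow(tab) == 0L) return(list())
  refs <- NULL
  if (!is.null(reference_fasta)) {
    refs <- Biostrings::readDNAStringSet(reference_fasta)
    names(refs) <- sub("\\s.*$", "", names(refs))
  }
  split_primer <- function(p, what, name) {
    m <- regmatches(p, regexec("^\\(([^)]*)\\)\\s*(.+)$", p))[[1L]]
    if (length(m) == 3L) return(list(overhang = m[2L], primer = gsub("\\s", "", m[3L])))
    warning(sprintf("assay %s: %s primer has no parseable overhang parentheses; treated as no overhang",
                    name, what))
    list(overhang = "", primer = gsub("\\s", "", p))
  }
  num <- function(x) as.numeric(gsub("[, ]", "", x))
  assays <- lapply(seq_len(nrow(tab)), function(i) {
    fp <- split_primer(tab$forward_primer[i], "forward", tab$name[i])
    rp <- split_primer(tab$reverse_primer[i], "reverse", tab$name[i])
    ref <- NULL
    if (!is.null(refs) && tab$name[i] %in% names(refs))
      ref <- as.character(refs[[tab$name[i]]])
    amplicon_assay(name = tab$name[i],
                   region_type = tolower(tab$type[i]),
                   chrom = as.character(tab$chrom[i]),
                   start = num(tab$start[i]), end = num(tab$end[i]),
                   forward_primer = fp$primer, reverse_primer = rp$primer,
                   forward_overhang = fp$overhang,
                   reverse_overhang = rp$overhang,
                   reference_seq = ref)
  })
  names(assays) <- tab$name
  if ("reported_length_bp" %in% names(tab)) {
    span <- vapply(assays, `[[`, 0, "length_bp")
    bad <- which(span != tab$reported_length_bp)
    if (length(bad))
      warning(sprintf(
        "assay(s) %s: coordinate span differs from reported length (coordinates likely include primer annealing sites)",
        paste(tab$name[bad], collapse = ", ")))
    for (i in seq_along(assays))
      assays[[i]]$reported_length_bp <- tab$reported_length_bp[i]
  }
  assays
}
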