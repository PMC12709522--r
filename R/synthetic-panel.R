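# A synthetic four-assay panel (two hyper, two hypo) with the lengths, CpG
# counts and contrast directions of the validated diagnostic loci. The
# amplicon sequences are generated, not genomic: they exist so the read
# caller, the simulators and the classifiers can be exercised end to end
# without a reference genome.

ILLUMINA_FWD_OVERHANG <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
ILLUMINA_REV_OVERHANG <- "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"

# Random amplicon with exactly n_cpg CpGs, all outside the primer regions.
make_synthetic_amplicon <- function(len, n_cpg, primer_len = 21L) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # remove accidental CpGs
  repeat {
    cg <- which(x[-len] == "C" & x[-1] == "G")
    if (!length(cg)) break
    x[cg + 1L] <- "A"
  }
  lo <- primer_len + 2L
  hi <- len - primer_len - 2L
  slots <- seq(lo, hi, by = 3L)
  if (length(slots) < n_cpg)
    stop_config("amplicon too short for %d CpGs", n_cpg)
  p <- sort(sample(slots, n_cpg))
  x[p] <- "C"
  x[p + 1L] <- "G"
  seq <- paste(x, collapse = "")
  stopifnot(identical(enumerate_cpg_sites(seq), as.integer(p)))
  seq
}

#' Synthetic diagnostic assay panel
#'
#' Builds four seeded synthetic amplicon assays mirroring the validated
#' panel's geometry — two hyper-methylated targets (n7: 268 bp / 40 CpGs,
#' n8: 204 bp / 23 CpGs) and two hypo-methylated targets (n11: 111 bp /
#' 7 CpGs, n13: 210 bp / 12 CpGs) — with 21-bp CpG-free primer regions.
#' Forward primers are the bisulfite-converted prefix of each amplicon and
#' reverse primers the reverse complement of the converted suffix, as in
#' bisulfite PCR design. Sequences are synthetic stand-ins, not genomic.
#'
#' @param seed integer seed for the sequence draw.
#' @return A named list of four [amplicon_assay()] objects.
#' @export
synthetic_assay_panel <- function(seed = 20231L) {
  geometry <- list(
    n7  = list(type = "hyper", len = 268L, n_cpg = 40L, chrom = "chr14"),
    n8  = list(type = "hyper", len = 204L, n_cpg = 23L, chrom = "chr17"),
    n11 = list(type = "hypo",  len = 111L, n_cpg = 7L,  chrom = "chr16"),
    n13 = list(type = "hypo",  len = 210L, n_cpg = 12L, chrom = "chr1"))
  with_seed(seed, {
    assays <- lapply(names(geometry), function(nm) {
      g <- geometry[[nm]]
      primer_len <- 21L
      seq <- make_synthetic_amplicon(g$len, g$n_cpg, primer_len)
      fwd <- chartr("C", "T", substr(seq, 1L, primer_len))
      rev <- revcomp_chr(chartr("C", "T",
                                substr(seq, g$len - primer_len + 1L, g$len)))
      start <- 1e6
      amplicon_assay(name = nm, region_type = g$type, chrom = g$chrom,
                     start = start, end = start + g$len,
                     forward_primer = fwd, reverse_primer = rev,
                     forward_overhang = ILLUMINA_FWD_OVERHANG,
                     reverse_overhang = ILLUMINA_REV_OVERHANG,
                     reference_seq = seq)
    })
    names(assays) <- names(geometry)
    assays
  })
}
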