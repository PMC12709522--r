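# Synthetic-data generation: per-tissue molecule archetypes, bisulfite
# amplicon reads with conversion noise and sequencing error, tissue mixtures,
# environmental degradation, and methylome compendia with planted
# brain-specific regions. Every generator is deterministic given its seed.

#' Tissue methylation profile for one assay
#'
#' A mixture of molecule archetypes: each archetype has a weight and a
#' per-CpG methylation probability vector. Models the bimodal per-read
#' methylation distributions targeted assays show (a dominant tissue-specific
#' epiallele plus background molecules).
#'
#' @param assay_name,tissue_label identifiers.
#' @param weights numeric archetype weights summing to 1.
#' @param probs list of per-CpG methylation probability vectors (all the same
#'   length, values in \[0,1\]).
#' @return A list of class `tissue_profile`.
#' @export
tissue_profile <- function(assay_name, tissue_label, weights, probs) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, length(weights) == length(probs))
  k <- unique(lengths(probs))
  stopifnot(length(k) == 1L, all(unlist(probs) >= 0), all(unlist(probs) <= 1))
  structure(list(assay_name = assay_name, tissue_label = tissue_label,
                 weights = weights, probs = probs, n_cpg = k),
            class = "tissue_profile")
}

#' Default brain / decoy profiles for an assay
#'
#' Brain: 90% of molecules follow the brain archetype (per-CpG methylation
#' probability `archetype_level`, 0.03 for hypo assays and mirrored to 0.97
#' for hyper assays) and 10% follow the decoy-like background. Decoys carry
#' the background only (0.9 for hypo assays, mirrored to 0.1 for hyper).
#' These defaults reproduce the qualitative bimodal read distributions of
#' targeted brain assays and are configurable, not measured ground truth.
#'
#' @param assay an [amplicon_assay()].
#' @param archetype_weight brain archetype weight (default 0.9).
#' @param archetype_level per-CpG methylation probability of the brain
#'   archetype on a hypo assay (default 0.03; mirrored for hyper).
#' @param background_level per-CpG methylation probability of background
#'   molecules on a hypo assay (default 0.9; mirrored for hyper).
#' @param tissue_label label for the generated profile.
#' @return A [tissue_profile()].
#' @export
brain_profile <- function(assay, archetype_weight = 0.9,
                          archetype_level = 0.03, background_level = 0.9,
                          tissue_label = "brain") {
  k <- length(assay$cpg_offsets)
  if (assay$region_type == "hyper") {
    archetype_level <- 1 - archetype_level
    background_level <- 1 - background_level
  }
  tissue_profile(assay$name, tissue_label,
                 weights = c(archetype_weight, 1 - archetype_weight),
                 probs = list(rep(archetype_level, k), rep(background_level, k)))
}

#' @rdname brain_profile
#' @export
decoy_profile <- function(assay, background_level = 0.9,
                          tissue_label = "decoy") {
  k <- length(assay$cpg_offsets)
  if (assay$region_type == "hyper") background_level <- 1 - background_level
  tissue_profile(assay$name, tissue_label, weights = 1,
                 probs = list(rep(background_level, k)))
}

#' Bisulfite / sequencing noise model
#'
#' @param conversion_efficiency probability an unmethylated C is converted to
#'   T (default 0.99).
#' @param inappropriate_conversion probability a methylated C is erroneously
#'   converted (default 0.005).
#' @param seq_error per-base substitution error rate (default 0.002).
#' @param base_quality constant Phred quality written to FASTQ (default 35).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(conversion_efficiency = 0.99,
                        inappropriate_conversion = 0.005, seq_error = 0.002,
                        base_quality = 35L) {
  rates <- c(conversion_efficiency, inappropriate_conversion, seq_error)
  stopifnot(all(rates >= 0), all(rates <= 1), base_quality >= 2)
  structure(list(conversion_efficiency = conversion_efficiency,
                 inappropriate_conversion = inappropriate_conversion,
                 seq_error = seq_error, base_quality = as.integer(base_quality)),
            class = "noise_model")
}

#' Environmental degradation specification
#'
#' Emulates burned / air-dried material: depth loss, molecule truncation
#' below full CpG coverage, and elevated substitution error.
#'
#' @param depth_factor fraction of read pairs retained (default 0.3).
#' @param truncation_prob probability a retained molecule is 3'-truncated so
#'   CpG coverage fails (default 0.2).
#' @param error_multiplier factor applied to the substitution rate
#'   (default 3).
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(depth_factor = 0.3, truncation_prob = 0.2,
                             error_multiplier = 3) {
  stopifnot(depth_factor > 0, depth_factor <= 1,
            truncation_prob >= 0, truncation_prob < 1, error_multiplier >= 1)
  structure(list(depth_factor = depth_factor,
                 truncation_prob = truncation_prob,
                 error_multiplier = error_multiplier),
            class = "degradation_spec")
}

#' Sample molecule methylation patterns from a tissue profile
#'
#' Chooses an archetype per molecule by weight, then sets each CpG
#' independently methylated with that archetype's per-CpG probability.
#'
#' @param profile a [tissue_profile()].
#' @param n number of molecules.
#' @return A list with `patterns` (n x k logical matrix) and `archetype`
#'   (integer vector).
#' @export
sample_molecule <- function(profile, n = 1L) {
  stopifnot(inherits(profile, "tissue_profile"), n >= 1)
  arch <- sample.int(length(profile$weights), n, replace = TRUE,
                     prob = profile$weights)
  pmat <- do.call(rbind, profile$probs)[arch, , drop = FALSE]
  patterns <- matrix(runif(n * profile$n_cpg) < pmat, nrow = n)
  list(patterns = patterns, archetype = arch)
}

# Resolve an IUPAC string into an n x len character matrix, sampling
# degenerate positions per molecule.
resolve_iupac <- function(seq, n) {
  cs <- chars(seq)
  mat <- matrix("", nrow = n, ncol = length(cs))
  for (j in seq_along(cs)) {
    exp <- IUPAC_CODES[[cs[j]]]
    if (is.null(exp)) stop_config("invalid IUPAC code in primer: %s", cs[j])
    mat[, j] <- if (length(exp) == 1L) exp else sample(exp, n, replace = TRUE)
  }
  mat
}

BASES <- c("A", "C", "G", "T")
# 3 alternative bases per original base, rows in BASES order.
ALT_BASES <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                   c("A", "C", "T"), c("A", "C", "G"))

# Substitute bases at `rate` in a character matrix/vector of bases.
substitute_errors_mat <- function(mat, rate) {
  if (rate <= 0) return(mat)
  hit <- which(runif(length(mat)) < rate & mat %in% BASES)
  if (length(hit)) {
    pick <- sample.int(3L, length(hit), replace = TRUE)
    mat[hit] <- ALT_BASES[cbind(match(mat[hit], BASES), pick)]
  }
  mat
}

collapse_rows <- function(mat) {
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

write_fastq <- function(seqs, ids, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Generate paired bisulfite amplicon reads for one sample
#'
#' Per molecule: a methylation pattern is drawn from the tissue profile; the
#' amplicon reference is bisulfite-converted per that pattern and the noise
#' model (non-CpG cytosines are modeled as unmethylated, so conversion
#' failures surface as retained non-CpG C at rate 1 - efficiency); primer
#' regions are overwritten by primer realizations (PCR erases the template
#' there); substitution errors are applied; and the molecule is emitted as a
#' primer-anchored R1/R2 pair of at most `read_length` bases (R2
#' reverse-complemented). Byte-deterministic given the seed.
#'
#' @param profile a [tissue_profile()].
#' @param assay an [amplicon_assay()] with `reference_seq`.
#' @param n number of molecules (read pairs).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param prefix file prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`,
#'   `<prefix>_truth.tsv`, `<prefix>_config.yaml`.
#' @param read_length read length (default 150).
#' @return Invisibly, a list with the output `paths` and the `truth`
#'   data.frame (`read_id`, `archetype`, `pattern`, `methylation_percent`).
#' @export
generate_reads <- function(profile, assay, n, noise = noise_model(), seed = 1L,
                           out_dir = tempdir(), prefix = NULL,
                           read_length = 150L) {
  if (n < 1) stop_config("n must be >= 1")
  stopifnot(inherits(assay, "amplicon_assay"))
  if (is.null(assay$reference_seq))
    stop_config("assay %s has no reference sequence", assay$name)
  prefix <- prefix %||% sprintf("%s_%s", assay$name, profile$tissue_label)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- chars(assay$reference_seq)
  L <- length(ref)
  off <- assay$cpg_offsets
  k <- length(off)
  non_cpg_c <- setdiff(which(ref == "C"), off)

  out <- with_seed(seed, {
    mol <- sample_molecule(profile, n)
    mat <- matrix(rep(ref, each = n), nrow = n)
    # CpG cytosines per pattern: methylated stays C unless inappropriately
    # converted; unmethylated reads T unless conversion fails.
    if (k > 0) {
      meth <- mol$patterns
      u <- matrix(runif(n * k), nrow = n)
      cpg_base <- ifelse(meth,
                         ifelse(u < noise$inappropriate_conversion, "T", "C"),
                         ifelse(u < noise$conversion_efficiency, "T", "C"))
      mat[, off] <- cpg_base
    }
    # non-CpG cytosines: unmethylated by assumption.
    if (length(non_cpg_c)) {
      u <- matrix(runif(n * length(non_cpg_c)), nrow = n)
      mat[, non_cpg_c] <- ifelse(u < noise$conversion_efficiency, "T", "C")
    }
    # primer regions come from the synthesized primers, not the template
    lf <- nchar(assay$forward_primer)
    lr <- nchar(assay$reverse_primer)
    if (lf > 0) mat[, seq_len(lf)] <- resolve_iupac(assay$forward_primer, n)
    if (lr > 0) mat[, (L - lr + 1L):L] <-
      resolve_iupac(revcomp_chr(assay$reverse_primer), n)
    mat <- substitute_errors_mat(mat, noise$seq_error)
    molecules <- collapse_rows(mat)
    r1 <- substr(molecules, 1L, min(read_length, L))
    r2 <- revcomp_vec(substr(molecules, max(1L, L - read_length + 1L), L))
    list(r1 = r1, r2 = r2, patterns = mol$patterns, archetype = mol$archetype)
  })

  ids <- sprintf("%s:mol%06d", prefix, seq_len(n))
  qc <- rawToChar(as.raw(33L + noise$base_quality))
  paths <- list(r1 = file.path(out_dir, paste0(prefix, "_R1.fastq")),
                r2 = file.path(out_dir, paste0(prefix, "_R2.fastq")),
                truth = file.path(out_dir, paste0(prefix, "_truth.tsv")),
                config = file.path(out_dir, paste0(prefix, "_config.yaml")))
  write_fastq(out$r1, ids, strrep(qc, nchar(out$r1)), paths$r1)
  write_fastq(out$r2, ids, strrep(qc, nchar(out$r2)), paths$r2)
  pattern_str <- if (k > 0) apply(out$patterns, 1, function(p)
    paste(as.integer(p), collapse = "")) else rep("", n)
  truth <- data.frame(read_id = ids, archetype = out$archetype,
                      pattern = pattern_str,
                      methylation_percent = if (k > 0)
                        rowMeans(out$patterns) else NA_real_,
                      stringsAsFactors = FALSE)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(list(
    operation = "generate_reads", assay = assay$name,
    tissue_label = profile$tissue_label, n = n, seed = seed,
    read_length = read_length, noise = unclass(noise)), paths$config)
  invisible(list(paths = paths, truth = truth))
}

#' Mix read sets by weight
#'
#' Draws `n_total` read pairs with replacement, each pair coming from
#' component i with probability `weights[i]`. Provenance is kept in the read
#' id (`|src=<i>` suffix). Emulates mixed tissue samples with weight
#' fractions converted 1:1 to read fractions.
#'
#' @param components list; each element a list with `r1`, `r2` FASTQ paths
#'   and `weight`.
#' @param n_total total pairs drawn.
#' @param seed integer seed.
#' @param out_dir,prefix outputs `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#' @return Invisibly, the output paths plus the per-read source index.
#' @export
mix_read_sets <- function(components, n_total, seed = 1L,
                          out_dir = tempdir(), prefix = "mix") {
  stopifnot(length(components) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- vapply(components, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-6) stop_config("component weights must sum to 1")
  pools <- lapply(components, function(cm) {
    r1 <- Biostrings::readDNAStringSet(cm$r1, format = "fastq",
                                       with.qualities = TRUE)
    r2 <- Biostrings::readDNAStringSet(cm$r2, format = "fastq",
                                       with.qualities = TRUE)
    if (length(r1) == 0L) stop_config("empty mix component: %s", cm$r1)
    list(s1 = as.character(r1),
         q1 = as.character(S4Vectors::mcols(r1)$qualities),
         s2 = as.character(r2),
         q2 = as.character(S4Vectors::mcols(r2)$qualities),
         ids = sub("\\s.*$", "", names(r1)))
  })
  sel <- with_seed(seed, {
    src <- sample.int(length(pools), n_total, replace = TRUE, prob = w)
    idx <- vapply(src, function(s)
      sample.int(length(pools[[s]]$ids), 1L), integer(1))
    list(src = src, idx = idx)
  })
  take <- function(field) mapply(function(s, i) pools[[s]][[field]][i],
                                 sel$src, sel$idx)
  ids <- sprintf("%s|src=%d", take("ids"), sel$src)
  paths <- list(r1 = file.path(out_dir, paste0(prefix, "_R1.fastq")),
                r2 = file.path(out_dir, paste0(prefix, "_R2.fastq")))
  write_fastq(take("s1"), ids, take("q1"), paths$r1)
  write_fastq(take("s2"), ids, take("q2"), paths$r2)
  invisible(list(paths = paths, source = sel$src))
}

#' Apply environmental degradation to a read set
#'
#' Read pairs are kept with probability `depth_factor`; kept molecules are
#' 3'-truncated with probability `truncation_prob` (the fragment is cut below
#' the last CpG, so CpG coverage fails downstream; R2 becomes the reverse
#' complement of the truncated fragment's tail); substitution error is raised
#' to `base_error * error_multiplier` by injecting the difference.
#'
#' @param fastq_r1,fastq_r2 input FASTQ paths.
#' @param spec a [degradation_spec()].
#' @param seed integer seed.
#' @param out_dir,prefix outputs `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#' @param assay optional [amplicon_assay()]; when supplied, truncation points
#'   are drawn between the forward primer end and the last CpG offset,
#'   otherwise uniformly within the read.
#' @param base_error substitution rate already present in the input
#'   (default 0.002).
#' @return Invisibly, the output paths and the number of pairs kept.
#' @export
apply_degradation <- function(fastq_r1, fastq_r2, spec = degradation_spec(),
                              seed = 1L, out_dir = tempdir(),
                              prefix = "degraded", assay = NULL,
                              base_error = 0.002) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- Biostrings::readDNAStringSet(fastq_r1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_r2, format = "fastq",
                                     with.qualities = TRUE)
  s1 <- as.character(r1); q1 <- as.character(S4Vectors::mcols(r1)$qualities)
  s2 <- as.character(r2); q2 <- as.character(S4Vectors::mcols(r2)$qualities)
  ids <- sub("\\s.*$", "", names(r1))
  n <- length(s1)
  res <- with_seed(seed, {
    keep <- which(runif(n) < spec$depth_factor)
    s1 <- s1[keep]; q1 <- q1[keep]; s2 <- s2[keep]; q2 <- q2[keep]
    ids <- ids[keep]
    trunc <- runif(length(keep)) < spec$truncation_prob
    if (any(trunc)) {
      len1 <- nchar(s1[trunc])
      lo <- if (!is.null(assay)) nchar(assay$forward_primer) + 1L else 30L
      hi <- if (!is.null(assay) && length(assay$cpg_offsets))
        max(assay$cpg_offsets) - 1L else pmax(lo + 1L, floor(0.6 * len1))
      tp <- pmin(pmax(lo, floor(runif(sum(trunc), lo, hi + 1))), len1)
      s1[trunc] <- substr(s1[trunc], 1L, tp)
      q1[trunc] <- substr(q1[trunc], 1L, tp)
      tail_start <- pmax(1L, tp - nchar(s2[trunc]) + 1L)
      s2[trunc] <- revcomp_vec(substr(s1[trunc], tail_start, tp))
      q2[trunc] <- substr(q1[trunc], tail_start, tp)
    }
    add_rate <- base_error * (spec$error_multiplier - 1)
    sub_seq <- function(x) {
      vapply(x, function(s) {
        cs <- substitute_errors_mat(chars(s), add_rate)
        paste(cs, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    if (add_rate > 0) {
      s1 <- sub_seq(s1)
      s2 <- sub_seq(s2)
    }
    list(s1 = s1, q1 = q1, s2 = s2, q2 = q2, ids = ids)
  })
  paths <- list(r1 = file.path(out_dir, paste0(prefix, "_R1.fastq")),
                r2 = file.path(out_dir, paste0(prefix, "_R2.fastq")))
  write_fastq(res$s1, res$ids, res$q1, paths$r1)
  write_fastq(res$s2, res$ids, res$q2, paths$r2)
  invisible(list(paths = paths, n_kept = length(res$ids)))
}

#' Compendium simulation specification
#'
#' @param n_positions number of CpG positions.
#' @param n_brain,n_decoy sample counts per group.
#' @param background_shape Beta(a, b) parameters for the per-position,
#'   per-group background mean (default c(0.6, 0.6): the bimodal marginal
#'   real methylomes show).
#' @param sample_concentration Beta concentration of per-sample values around
#'   the group mean (default 30).
#' @param planted_regions list; each element a list with `start_index`,
#'   `n_cpg` (>= 5), `mode` (`"hypo"`/`"hyper"`), `brain_level`,
#'   `decoy_level`.
#' @param independent_backgrounds if `FALSE` (default) brain and decoy share
#'   one background mean per position, as tissues share methylation state at
#'   most CpGs; `TRUE` draws the group means independently.
#' @param decoy_missing_rate per-position probability a decoy sample lacks
#'   coverage (default 0).
#' @param chrom synthetic chromosome name.
#' @param seed integer seed.
#' @return A list of class `compendium_sim_spec`.
#' @export
compendium_sim_spec <- function(n_positions = 300L, n_brain = 4L,
                                n_decoy = 8L, background_shape = c(0.6, 0.6),
                                sample_concentration = 30,
                                planted_regions = list(),
                                independent_backgrounds = FALSE,
                                decoy_missing_rate = 0, chrom = "chrS",
                                seed = 1L) {
  stopifnot(n_positions >= 1, n_brain >= 1, n_decoy >= 1,
            length(background_shape) == 2L, all(background_shape > 0),
            decoy_missing_rate >= 0, decoy_missing_rate < 1)
  for (pr in planted_regions) {
    stopifnot(!is.null(pr$start_index), !is.null(pr$n_cpg))
    if (pr$n_cpg < 5L)
      stop_config("planted region must hold at least 5 CpGs")
    if (pr$start_index < 1L || pr$start_index + pr$n_cpg - 1L > n_positions)
      stop_config("planted region indices out of range")
  }
  structure(list(n_positions = as.integer(n_positions),
                 n_brain = as.integer(n_brain), n_decoy = as.integer(n_decoy),
                 background_shape = background_shape,
                 sample_concentration = sample_concentration,
                 planted_regions = planted_regions,
                 independent_backgrounds = isTRUE(independent_backgrounds),
                 decoy_missing_rate = decoy_missing_rate,
                 chrom = chrom, seed = as.integer(seed)),
            class = "compendium_sim_spec")
}

#' Generate a synthetic multi-tissue methylome compendium
#'
#' Draws per-position, per-group background means from the background Beta,
#' per-sample values from a Beta concentrated around the group mean,
#' overwrites planted regions with their brain/decoy levels (positions inside
#' a planted region are re-spaced so at least 5 CpGs fall within 300 bp), and
#' writes one bedGraph table per sample plus a manifest and a truth BED of
#' planted regions. Deterministic given the seed.
#'
#' @param spec a [compendium_sim_spec()].
#' @param out_dir output directory.
#' @return Invisibly, a list with `manifest` (path), `truth_bed` (path),
#'   `truth_regions` (data.frame), and `positions`.
#' @export
generate_compendium <- function(spec = compendium_sim_spec(),
                                out_dir = tempdir()) {
  stopifnot(inherits(spec, "compendium_sim_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  np <- spec$n_positions
  res <- with_seed(spec$seed, {
    gaps <- sample(10:60, np - 1L, replace = TRUE)
    planted_idx <- integer(0)
    for (pr in spec$planted_regions) {
      idx <- pr$start_index:(pr$start_index + pr$n_cpg - 1L)
      if (length(idx) > 1L)  # compress so the run fits in the span window
        gaps[idx[-length(idx)]] <- sample(10:35, length(idx) - 1L,
                                          replace = TRUE)
      planted_idx <- c(planted_idx, idx)
    }
    pos <- cumsum(c(1000L, gaps))
    a <- spec$background_shape[1]; b <- spec$background_shape[2]
    mu_brain <- rbeta(np, a, b)
    mu_decoy <- if (spec$independent_backgrounds) rbeta(np, a, b) else mu_brain
    for (pr in spec$planted_regions) {
      idx <- pr$start_index:(pr$start_index + pr$n_cpg - 1L)
      mode <- pr$mode %||% "hypo"
      bl <- pr$brain_level %||% if (mode == "hypo") 0.02 else 0.95
      dl <- pr$decoy_level %||% if (mode == "hypo") 0.95 else 0.02
      mu_brain[idx] <- bl
      mu_decoy[idx] <- dl
    }
    nu <- spec$sample_concentration
    clamp <- function(x) pmin(pmax(x, 0.005), 0.995)
    draw <- function(mu, ns) {
      m <- clamp(mu)
      matrix(rbeta(np * ns, rep(m, ns) * nu, rep(1 - m, ns) * nu), nrow = np)
    }
    vb <- draw(mu_brain, spec$n_brain)
    vd <- draw(mu_decoy, spec$n_decoy)
    miss <- matrix(runif(np * spec$n_decoy) < spec$decoy_missing_rate,
                   nrow = np)
    list(pos = pos, vb = vb, vd = vd, miss = miss)
  })
  ids <- c(sprintf("brain%02d", seq_len(spec$n_brain)),
           sprintf("decoy%02d", seq_len(spec$n_decoy)))
  groups <- c(rep("brain", spec$n_brain), rep("decoy", spec$n_decoy))
  paths <- file.path(out_dir, paste0(ids, ".bedgraph"))
  for (j in seq_len(spec$n_brain)) {
    write_methylation_table(data.frame(
      chrom = spec$chrom, start = res$pos, end = res$pos + 1,
      methylation_fraction = res$vb[, j]), paths[j])
  }
  for (j in seq_len(spec$n_decoy)) {
    keep <- !res$miss[, j]
    write_methylation_table(data.frame(
      chrom = spec$chrom, start = res$pos[keep], end = res$pos[keep] + 1,
      methylation_fraction = res$vd[keep, j]), paths[spec$n_brain + j])
  }
  manifest <- data.frame(sample_id = ids, tissue_label = groups,
                         group = groups, path = paths,
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_sample_manifest(manifest, manifest_path)
  truth <- do.call(rbind, lapply(seq_along(spec$planted_regions), function(i) {
    pr <- spec$planted_regions[[i]]
    idx <- pr$start_index:(pr$start_index + pr$n_cpg - 1L)
    data.frame(chrom = spec$chrom, start = res$pos[idx[1]],
               end = res$pos[idx[length(idx)]] + 1,
               name = sprintf("planted_%d", i),
               mode = pr$mode %||% "hypo", stringsAsFactors = FALSE)
  }))
  truth_bed <- file.path(out_dir, "truth_regions.bed")
  if (is.null(truth)) {
    writeLines(character(0), truth_bed)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", truth$chrom,
                       as.integer(truth$start), as.integer(truth$end),
                       truth$name), truth_bed)
  }
  write_run_config(list(operation = "generate_compendium",
                        spec = unclass(spec)),
                   file.path(out_dir, "compendium_config.yaml"))
  invisible(list(manifest = manifest_path, truth_bed = truth_bed,
                 truth_regions = truth, positions = res$pos))
}
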