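# Per-position methylation tables (bedGraph dialect), sample manifests, and
# assembly of the positions-by-samples compendium used for marker discovery.

#' Read a per-position methylation table
#'
#' Parses a bedGraph-style TSV (chrom, start, end, methylation, optional
#' coverage, optional strand) as produced by methylation extractors. Track and
#' comment lines are skipped. Coordinates are 0-based half-open; a single-CpG
#' record spans one base, keyed by its plus-strand cytosine coordinate. When a
#' strand column is present, minus-strand records are re-keyed to the
#' plus-strand C (coordinate - 1) and averaged with any plus-strand record,
#' coverage-weighted when coverage is available (CpG methylation is
#' strand-symmetric).
#'
#' @param path file path.
#' @param percent_scale `"auto"` (default; treat the methylation column as
#'   percent when any value exceeds 1), `"percent"`, or `"fraction"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `methylation_fraction` (in \[0, 1\]) and, when present in the input,
#'   `coverage`, ordered as in the file (after any strand collapsing).
#' @export
read_methylation_table <- function(path, percent_scale = c("auto", "percent", "fraction")) {
  percent_scale <- match.arg(percent_scale)
  if (!file.exists(path)) stop_config("methylation table not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(track|#|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      methylation_fraction = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop_config("malformed methylation table line %d in %s: fewer than 4 fields",
                lineno[which(nf < 4L)[1L]], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  meth  <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(meth))
  if (length(bad)) {
    stop_config("malformed methylation table line %d in %s: non-numeric coordinate or methylation",
                lineno[bad[1L]], path)
  }
  if (any(start >= end)) {
    stop_config("invalid interval at line %d in %s: start >= end",
                lineno[which(start >= end)[1L]], path)
  }
  coverage <- NULL
  if (all(nf >= 5L)) {
    cov5 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (all(is.finite(cov5))) coverage <- cov5
  }
  strand <- NULL
  if (all(nf >= 6L)) {
    s6 <- vapply(fields, `[[`, "", 6L)
    if (all(s6 %in% c("+", "-"))) strand <- s6
  }
  is_percent <- switch(percent_scale,
    percent = TRUE, fraction = FALSE, auto = any(meth > 1))
  if (is_percent) {
    if (any(meth < 0 | meth > 100))
      stop_config("methylation outside [0,100] at line %d in %s",
                  lineno[which(meth < 0 | meth > 100)[1L]], path)
    meth <- meth / 100
  } else if (any(meth < 0 | meth > 1)) {
    stop_config("methylation outside [0,1] at line %d in %s",
                lineno[which(meth < 0 | meth > 1)[1L]], path)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    methylation_fraction = meth, stringsAsFactors = FALSE)
  if (!is.null(coverage)) out$coverage <- coverage
  if (!is.null(strand)) out <- collapse_strands(out, strand)
  rownames(out) <- NULL
  out
}

# Re-key minus-strand CpG records to the plus-strand cytosine and average.
collapse_strands <- function(df, strand) {
  minus <- strand == "-"
  df$start[minus] <- df$start[minus] - 1
  df$end[minus] <- df$end[minus] - 1
  key <- paste(df$chrom, df$start)
  if (!anyDuplicated(key)) return(df)
  w <- if (!is.null(df$coverage)) df$coverage else rep(1, nrow(df))
  w[w <= 0] <- 1
  agg_m <- tapply(df$methylation_fraction * w, key, sum) / tapply(w, key, sum)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$methylation_fraction <- as.numeric(agg_m[paste(out$chrom, out$start)])
  if (!is.null(df$coverage)) out$coverage <- as.numeric(tapply(df$coverage, key, sum)[paste(out$chrom, out$start)])
  out
}

#' Write a per-position methylation table
#'
#' Inverse of [read_methylation_table()]: emits a bedGraph-style TSV. Reading
#' the written file back reproduces the records (to text round-trip precision).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`,
#'   `methylation_fraction`, optional `coverage`.
#' @param path output path.
#' @param percent_scale write the methylation column as percent (default) or
#'   as a fraction.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(records, path, percent_scale = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "methylation_fraction") %in% names(records)))
  if (any(records$start >= records$end)) stop_config("invalid records: start >= end")
  if (any(records$methylation_fraction < 0 | records$methylation_fraction > 1))
    stop_config("invalid records: methylation_fraction outside [0,1]")
  meth <- if (percent_scale) records$methylation_fraction * 100 else records$methylation_fraction
  cols <- list(records$chrom, format(records$start, scientific = FALSE, trim = TRUE),
               format(records$end, scientific = FALSE, trim = TRUE),
               sprintf("%.17g", meth))
  if (!is.null(records$coverage)) cols <- c(cols, list(format(records$coverage, trim = TRUE)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' A manifest labels each methylation table with a sample id, a tissue label,
#' and a group (`brain` or `decoy`). TSV with header
#' `sample_id  tissue_label  group  path`.
#'
#' @param path manifest path.
#' @return A `data.frame` with those four columns.
#' @export
read_sample_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue_label", "group", "path")
  if (!all(required %in% names(m)))
    stop_config("manifest must have columns: %s", paste(required, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop_config("duplicate sample_id in manifest")
  if (!all(m$group %in% c("brain", "decoy")))
    stop_config("manifest group must be 'brain' or 'decoy'")
  m
}

#' @rdname read_sample_manifest
#' @param manifest data.frame as returned by [read_sample_manifest()].
#' @export
write_sample_manifest <- function(manifest, path) {
  write.table(manifest[, c("sample_id", "tissue_label", "group", "path")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a positions-by-samples methylation compendium
#'
#' Reads every sample's methylation table and builds the matrix consumed by
#' marker discovery. A position is retained iff it is covered in every brain
#' sample and in at least `min_decoy_coverage_fraction` of the decoy samples;
#' decoy values missing at a retained position are `NA`.
#'
#' @param manifest data.frame with columns `sample_id`, `tissue_label`,
#'   `group` (`brain`/`decoy`), `path`; or a manifest file path.
#' @param min_decoy_coverage_fraction minimum fraction of decoy samples that
#'   must cover a position (default 0.8).
#' @param percent_scale passed to [read_methylation_table()].
#' @return A `methyl_compendium`: list with `positions` (data.frame `chrom`,
#'   `start`, sorted, unique), `values` (numeric matrix positions x samples),
#'   and `groups` (named character vector).
#' @export
build_compendium <- function(manifest, min_decoy_coverage_fraction = 0.8,
                             percent_scale = "auto") {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read_sample_manifest(manifest)
  if (!any(manifest$group == "brain"))
    stop_config("manifest has no brain samples")
  if (!any(manifest$group == "decoy"))
    stop_config("manifest has no decoy samples")
  stopifnot(min_decoy_coverage_fraction >= 0, min_decoy_coverage_fraction <= 1)

  tabs <- lapply(seq_len(nrow(manifest)), function(i)
    read_methylation_table(manifest$path[i], percent_scale))
  names(tabs) <- manifest$sample_id

  keys <- lapply(tabs, function(t) paste(t$chrom, t$start, sep = ":"))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  brain_ids <- manifest$sample_id[manifest$group == "brain"]
  decoy_ids <- manifest$sample_id[manifest$group == "decoy"]

  cover <- vapply(keys, function(k) all_keys %in% k,
                  logical(length(all_keys)))
  if (is.null(dim(cover))) cover <- matrix(cover, nrow = length(all_keys))
  colnames(cover) <- manifest$sample_id
  in_all_brain <- rowSums(cover[, brain_ids, drop = FALSE]) == length(brain_ids)
  decoy_frac <- rowSums(cover[, decoy_ids, drop = FALSE]) / length(decoy_ids)
  retained <- all_keys[in_all_brain & decoy_frac >= min_decoy_coverage_fraction]
  if (length(retained) == 0L)
    return(structure(list(
      positions = data.frame(chrom = character(), start = integer()),
      values = matrix(numeric(), 0, nrow(manifest),
                      dimnames = list(NULL, manifest$sample_id)),
      groups = setNames(manifest$group, manifest$sample_id)),
      class = "methyl_compendium"))

  parts <- do.call(rbind, strsplit(retained, ":", fixed = TRUE))
  pos <- data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
                    stringsAsFactors = FALSE)
  ord <- order(pos$chrom, pos$start)
  pos <- pos[ord, , drop = FALSE]
  retained <- retained[ord]
  rownames(pos) <- NULL

  values <- matrix(NA_real_, nrow = length(retained), ncol = nrow(manifest),
                   dimnames = list(retained, manifest$sample_id))
  for (sid in manifest$sample_id) {
    t <- tabs[[sid]]
    k <- paste(t$chrom, t$start, sep = ":")
    hit <- match(retained, k)
    values[, sid] <- t$methylation_fraction[hit]
  }
  structure(list(positions = pos, values = values,
                 groups = setNames(manifest$group, manifest$sample_id)),
            class = "methyl_compendium")
}

#' @export
print.methyl_compendium <- function(x, ...) {
  cat(sprintf("methylation compendium: %d positions x %d samples (%d brain, %d decoy)\n",
              nrow(x$positions), ncol(x$values),
              sum(x$groups == "brain"), sum(x$groups == "decoy")))
  cat(sprintf("  missing decoy entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}
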