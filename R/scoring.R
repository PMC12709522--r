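# Per-position hypo/hyper/informativeness scoring of the compendium.
#
# The score measures the weighted distance of a position from the ideal
# brain-vs-decoy methylation contrast (hypo mode: brain fully unmethylated,
# decoys fully methylated; hyper mode mirrored). Deviations from the ideal are
# penalized logistically so that major exceptions dominate; the maximum
# attainable score is 0, at the ideal contrast.

#' Scoring configuration for marker discovery
#'
#' @param penalty_amplitude amplitude A of the logistic penalty (default 4).
#' @param penalty_steepness steepness k of the logistic penalty (default 15).
#' @param penalty_midpoint midpoint c of the logistic penalty, in (0,1)
#'   (default 0.5): deviations beyond this are "major exceptions".
#' @param weight_brain,weight_decoy group weights in the score (default 1).
#' @param score_floor informativeness floor for a CpG to qualify for region
#'   membership (default -2).
#' @param min_cpg minimum CpGs per candidate region (default 5).
#' @param max_span_bp maximum first-to-last CpG span of a region (default 300).
#' @param top_fraction fraction of best member CpGs averaged in the region
#'   score (default 0.5).
#' @param cpg_count_bonus gamma, weight of the log2 CpG-count bonus in the
#'   region score (default 0.5).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(penalty_amplitude = 4, penalty_steepness = 15,
                           penalty_midpoint = 0.5, weight_brain = 1,
                           weight_decoy = 1, score_floor = -2, min_cpg = 5L,
                           max_span_bp = 300L, top_fraction = 0.5,
                           cpg_count_bonus = 0.5) {
  stopifnot(penalty_amplitude > 0, penalty_steepness > 0,
            penalty_midpoint > 0, penalty_midpoint < 1,
            min_cpg >= 2, max_span_bp > 0,
            top_fraction > 0, top_fraction <= 1, cpg_count_bonus >= 0)
  structure(list(penalty_amplitude = penalty_amplitude,
                 penalty_steepness = penalty_steepness,
                 penalty_midpoint = penalty_midpoint,
                 weight_brain = weight_brain, weight_decoy = weight_decoy,
                 score_floor = score_floor, min_cpg = as.integer(min_cpg),
                 max_span_bp = as.integer(max_span_bp),
                 top_fraction = top_fraction,
                 cpg_count_bonus = cpg_count_bonus),
            class = "scoring_config")
}

#' Logistic deviation penalty
#'
#' Penalty applied to a methylation deviation d in \[0,1\]:
#' `L(d) = d + A * (sigmoid(k * (d - c)) - sigmoid(-k * c))`. Anchored at
#' `L(0) = 0` and strictly increasing, so small deviations cost roughly their
#' magnitude while deviations beyond the midpoint (major exceptions) incur an
#' additional, logistically switched cost of up to A.
#'
#' @param d numeric vector of deviations in \[0,1\].
#' @param config a [scoring_config()].
#' @return Numeric vector of penalties, same length as `d`.
#' @export
logistic_penalty <- function(d, config = scoring_config()) {
  if (any(d < 0 | d > 1, na.rm = TRUE)) stop_config("deviation outside [0,1]")
  A <- config$penalty_amplitude
  k <- config$penalty_steepness
  c0 <- config$penalty_midpoint
  d + A * (plogis(k * (d - c0)) - plogis(-k * c0))
}

#' Score one position for brain-specific methylation
#'
#' Hypo mode measures closeness to "all brain unmethylated, all decoys
#' methylated": brain deviations are the brain fractions themselves and decoy
#' deviations are one minus the decoy fractions. Hyper mode mirrors both. The
#' score is minus the weighted sum of group-mean penalties, hence is always
#' at most 0 and equals 0 only at the ideal contrast.
#'
#' @param brain_fracs,decoy_fracs numeric vectors of methylation fractions in
#'   \[0,1\]; `NA` decoy values are ignored.
#' @param mode `"hypo"` or `"hyper"`.
#' @param config a [scoring_config()].
#' @return A single score <= 0.
#' @export
score_position <- function(brain_fracs, decoy_fracs, mode = c("hypo", "hyper"),
                           config = scoring_config()) {
  mode <- match.arg(mode)
  decoy_fracs <- decoy_fracs[!is.na(decoy_fracs)]
  if (length(brain_fracs) == 0L || anyNA(brain_fracs))
    stop_config("brain fractions must be non-empty and complete")
  if (length(decoy_fracs) == 0L) stop_config("no decoy values at position")
  if (any(c(brain_fracs, decoy_fracs) < 0 | c(brain_fracs, decoy_fracs) > 1))
    stop_config("methylation fractions outside [0,1]")
  if (mode == "hypo") {
    bdev <- brain_fracs
    ddev <- 1 - decoy_fracs
  } else {
    bdev <- 1 - brain_fracs
    ddev <- decoy_fracs
  }
  # + 0 normalizes IEEE negative zero at the ideal contrast
  -(config$weight_brain * mean(logistic_penalty(bdev, config)) +
    config$weight_decoy * mean(logistic_penalty(ddev, config))) + 0
}

#' Score every position of a compendium
#'
#' Computes hypo, hyper, and informativeness (= pairwise max) scores for each
#' compendium position. Missing decoy values are ignored (group means are over
#' present values); positions with no present decoy value are skipped with a
#' warning.
#'
#' @param compendium a `methyl_compendium` from [build_compendium()].
#' @param config a [scoring_config()].
#' @return A `data.frame` with columns `chrom`, `pos`, `hypo_score`,
#'   `hyper_score`, `informativeness`, sorted by (chrom, pos).
#' @export
score_compendium <- function(compendium, config = scoring_config()) {
  stopifnot(inherits(compendium, "methyl_compendium"))
  v <- compendium$values
  brain <- v[, compendium$groups == "brain", drop = FALSE]
  decoy <- v[, compendium$groups == "decoy", drop = FALSE]
  n_dec <- rowSums(!is.na(decoy))
  keep <- n_dec > 0
  if (any(!keep))
    warning(sprintf("%d position(s) with no decoy values skipped", sum(!keep)))
  brain <- brain[keep, , drop = FALSE]
  decoy <- decoy[keep, , drop = FALSE]

  mean_pen <- function(devmat) {
    p <- logistic_penalty(as.vector(devmat), config)
    rowMeans(matrix(p, nrow = nrow(devmat)), na.rm = TRUE)
  }
  wb <- config$weight_brain
  wd <- config$weight_decoy
  hypo <- -(wb * mean_pen(brain) + wd * mean_pen(1 - decoy))
  hyper <- -(wb * mean_pen(1 - brain) + wd * mean_pen(decoy))
  data.frame(chrom = compendium$positions$chrom[keep],
             pos = compendium$positions$start[keep],
             hypo_score = hypo, hyper_score = hyper,
             informativeness = pmax(hypo, hyper),
             stringsAsFactors = FALSE)
}

#' Write a per-position score table
#'
#' @param scores data.frame from [score_compendium()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
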