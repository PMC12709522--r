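# Sample-level classification from per-read methylation percentages, read-
# level decision-tree evaluation, resampling detection sensitivity, and
# multi-assay consensus.

#' Classifier configuration
#'
#' @param hypo_read_threshold a read of a hypo assay passes when its
#'   methylation percent is at most this (default 0.1, inclusive).
#' @param hyper_read_threshold a read of a hyper assay passes when its
#'   methylation percent is at least this (default 0.9, inclusive).
#' @param min_passing_fraction a sample is positive when at least this
#'   fraction of its valid reads passes (default 0.05, inclusive).
#' @param test_fraction held-out fraction for tree evaluation (default 0.2).
#' @param tree_max_depth decision-tree depth limit (default 3).
#' @param resample_reads reads drawn per resampling replicate (default 1e5).
#' @param seed RNG seed for splits and resampling.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(hypo_read_threshold = 0.1,
                              hyper_read_threshold = 0.9,
                              min_passing_fraction = 0.05,
                              test_fraction = 0.2, tree_max_depth = 3L,
                              resample_reads = 100000L, seed = 1L) {
  stopifnot(hypo_read_threshold >= 0, hypo_read_threshold <= 1,
            hyper_read_threshold >= 0, hyper_read_threshold <= 1,
            min_passing_fraction >= 0, min_passing_fraction <= 1,
            test_fraction > 0, test_fraction < 1, tree_max_depth >= 1)
  structure(list(hypo_read_threshold = hypo_read_threshold,
                 hyper_read_threshold = hyper_read_threshold,
                 min_passing_fraction = min_passing_fraction,
                 test_fraction = test_fraction,
                 tree_max_depth = as.integer(tree_max_depth),
                 resample_reads = as.integer(resample_reads),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

passing_reads <- function(percents, assay_type, config) {
  if (assay_type == "hypo") percents <= config$hypo_read_threshold
  else percents >= config$hyper_read_threshold
}

#' Classify a sample from its valid reads
#'
#' A read passes when its methylation percent is at most
#' `hypo_read_threshold` (hypo assay) or at least `hyper_read_threshold`
#' (hyper assay); the sample is positive when the passing fraction reaches
#' `min_passing_fraction`. A discarded read set (or one with zero valid
#' reads) yields a `discarded` verdict with passing fraction reported as 0
#' and a QC flag.
#'
#' @param read_set a `sample_read_set` from [process_sample()], or a numeric
#'   vector of per-read methylation percents (treated as the valid reads of a
#'   non-discarded sample).
#' @param assay_type `"hypo"` or `"hyper"`; defaults to the read set's own
#'   type when available.
#' @param config a [classifier_config()].
#' @param sample_id,assay_name identifiers used when `read_set` is a numeric
#'   vector.
#' @return A `sample_verdict`: `n_valid`, `passing_fraction`, `verdict`
#'   (`positive`/`negative`/`discarded`), `qc_flags`.
#' @export
classify_sample <- function(read_set, assay_type = NULL,
                            config = classifier_config(),
                            sample_id = "sample", assay_name = "assay") {
  if (inherits(read_set, "sample_read_set")) {
    percents <- read_set$valid_calls$methylation_percent
    discarded <- read_set$discarded
    sample_id <- read_set$sample_id
    assay_name <- read_set$assay_name
    assay_type <- assay_type %||% read_set$region_type
  } else {
    percents <- as.numeric(read_set)
    discarded <- length(percents) == 0L
  }
  if (is.null(assay_type)) stop_config("assay_type is required")
  assay_type <- match.arg(assay_type, c("hypo", "hyper"))
  qc <- character(0)
  n <- length(percents)
  if (n == 0L) {
    pf <- 0
    qc <- c(qc, "no valid reads; passing fraction undefined, reported as 0")
  } else {
    pf <- mean(passing_reads(percents, assay_type, config))
  }
  verdict <- if (discarded) "discarded"
    else if (pf >= config$min_passing_fraction) "positive" else "negative"
  structure(list(sample_id = sample_id, assay_name = assay_name,
                 assay_type = assay_type, n_valid = n,
                 passing_fraction = pf, verdict = verdict, qc_flags = qc),
            class = "sample_verdict")
}

#' @export
print.sample_verdict <- function(x, ...) {
  cat(sprintf("%s / %s (%s): %s  [passing %.3f of %d valid reads]\n",
              x$sample_id, x$assay_name, x$assay_type, toupper(x$verdict),
              x$passing_fraction, x$n_valid))
  for (f in x$qc_flags) cat("  flag:", f, "\n")
  invisible(x)
}

f1_score <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# Percent-threshold baseline: direction and cut chosen on the training split
# to maximize F1 for the brain class.
fit_percent_baseline <- function(percent, truth) {
  cand <- sort(unique(percent))
  cuts <- c(cand[1] - 1e-9, (head(cand, -1) + tail(cand, -1)) / 2,
            cand[length(cand)] + 1e-9)
  best <- list(f1 = -1, cut = cuts[1], dir = "le")
  for (dir in c("le", "ge")) {
    for (ct in cuts) {
      pred <- if (dir == "le") ifelse(percent <= ct, "brain", "non_brain")
              else ifelse(percent >= ct, "brain", "non_brain")
      f <- f1_score(pred, truth, "brain")
      if (f$f1 > best$f1) best <- list(f1 = f$f1, cut = ct, dir = dir)
    }
  }
  best
}

predict_percent_baseline <- function(fit, percent) {
  if (fit$dir == "le") ifelse(percent <= fit$cut, "brain", "non_brain")
  else ifelse(percent >= fit$cut, "brain", "non_brain")
}

#' Train and evaluate a read-level decision tree
#'
#' Fits a depth-limited classification tree on per-CpG binary methylation
#' states (brain vs non-brain labels), using a seeded stratified split with
#' `test_fraction` held out. Precision and recall for the brain class are
#' computed on the held-out reads and compared against a percent-threshold
#' baseline whose direction and cut maximize F1 on the training split. The
#' tree is flagged as improving only when its held-out F1 exceeds the
#' baseline's by more than 0.01.
#'
#' @param states 0/1 matrix (reads x CpGs) of methylation states.
#' @param labels vector with values `"brain"` / `"non_brain"` (anything not
#'   `"brain"` is treated as non-brain).
#' @param config a [classifier_config()].
#' @return A `tree_metrics` list: `precision`, `recall`, `f1`,
#'   `baseline_precision`, `baseline_recall`, `baseline_f1`, `tree_improves`,
#'   `n_train`, `n_test`, and the fitted `tree`.
#' @export
train_read_classifier <- function(states, labels, config = classifier_config()) {
  states <- as.matrix(states)
  labels <- ifelse(labels == "brain", "brain", "non_brain")
  if (length(unique(labels)) < 2L)
    stop_config("both classes must be present to train a read classifier")
  stopifnot(nrow(states) == length(labels))
  colnames(states) <- sprintf("cpg%02d", seq_len(ncol(states)))
  df <- data.frame(label = factor(labels, levels = c("brain", "non_brain")),
                   states, check.names = FALSE)
  test_idx <- with_seed(config$seed, {
    unlist(lapply(split(seq_len(nrow(df)), df$label), function(ix)
      sample(ix, round(length(ix) * config$test_fraction))))
  })
  train <- df[-test_idx, , drop = FALSE]
  test <- df[test_idx, , drop = FALSE]

  fit <- rpart::rpart(label ~ ., data = train, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = config$tree_max_depth, cp = 0,
                        minsplit = 20, xval = 0))
  pred <- as.character(predict(fit, test, type = "class"))
  tr <- f1_score(pred, as.character(test$label), "brain")

  pct_train <- rowMeans(train[, -1, drop = FALSE])
  pct_test <- rowMeans(test[, -1, drop = FALSE])
  base_fit <- fit_percent_baseline(pct_train, as.character(train$label))
  base_pred <- predict_percent_baseline(base_fit, pct_test)
  bl <- f1_score(base_pred, as.character(test$label), "brain")

  structure(list(precision = tr$precision, recall = tr$recall, f1 = tr$f1,
                 baseline_precision = bl$precision,
                 baseline_recall = bl$recall, baseline_f1 = bl$f1,
                 tree_improves = tr$f1 > bl$f1 + 0.01,
                 n_train = nrow(train), n_test = nrow(test), tree = fit),
            class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf("read-level tree:      precision %.3f recall %.3f F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("percent baseline:     precision %.3f recall %.3f F1 %.3f\n",
              x$baseline_precision, x$baseline_recall, x$baseline_f1))
  cat(sprintf("tree improves on percent baseline (> 0.01 F1): %s\n",
              x$tree_improves))
  invisible(x)
}

#' Detection sensitivity by read resampling
#'
#' Emulates samples of `config$resample_reads` reads drawn with replacement,
#' each read coming from the brain pool with probability `brain_fraction` and
#' from the decoy pool otherwise, classifies each resampled sample with
#' [classify_sample()], and reports the fraction of positive verdicts.
#' Seeded and reproducible.
#'
#' @param brain_pool,decoy_pool numeric vectors of per-read methylation
#'   percents.
#' @param brain_fraction mixing fraction f in \[0,1\].
#' @param reps number of replicates (>= 1).
#' @param assay_type `"hypo"` or `"hyper"`.
#' @param config a [classifier_config()]; `config$seed` seeds the draws.
#' @return The detection rate (positives / reps).
#' @export
simulate_detection <- function(brain_pool, decoy_pool, brain_fraction,
                               reps = 50L, assay_type = c("hypo", "hyper"),
                               config = classifier_config()) {
  assay_type <- match.arg(assay_type)
  if (reps < 1) stop_config("reps must be >= 1")
  if (length(brain_pool) == 0L || length(decoy_pool) == 0L)
    stop_config("read pools must be non-empty")
  stopifnot(brain_fraction >= 0, brain_fraction <= 1)
  n <- config$resample_reads
  with_seed(config$seed, {
    pos <- vapply(seq_len(reps), function(r) {
      nb <- rbinom(1L, n, brain_fraction)
      draws <- c(sample(brain_pool, nb, replace = TRUE),
                 sample(decoy_pool, n - nb, replace = TRUE))
      v <- classify_sample(draws, assay_type, config)
      v$verdict == "positive"
    }, logical(1))
    mean(pos)
  })
}

#' Combine per-assay verdicts into a consensus report
#'
#' All non-discarded assays positive yields `brain_detected`; all negative
#' yields `brain_not_detected`; any positive/negative contradiction yields
#' `rejected`. When every positive comes from a single assay type (only hypo
#' or only hyper) while the other type was tested and negative, a
#' bisulfite-efficiency QC flag is added (a conversion-efficiency deviation
#' can fake only one assay type). All verdicts discarded yields `rejected`
#' with an insufficient-reads flag.
#'
#' @param verdicts list of `sample_verdict` objects (from
#'   [classify_sample()]) across assays.
#' @return A `consensus_report`: `per_assay` data.frame, `overall`
#'   (`brain_detected`/`brain_not_detected`/`rejected`), `qc_flags`.
#' @export
consensus_verdict <- function(verdicts) {
  stopifnot(length(verdicts) >= 1L)
  per <- data.frame(
    sample_id = vapply(verdicts, `[[`, "", "sample_id"),
    assay_name = vapply(verdicts, `[[`, "", "assay_name"),
    assay_type = vapply(verdicts, `[[`, "", "assay_type"),
    n_valid = vapply(verdicts, function(v) as.integer(v$n_valid), integer(1)),
    passing_fraction = vapply(verdicts, `[[`, 0, "passing_fraction"),
    verdict = vapply(verdicts, `[[`, "", "verdict"),
    stringsAsFactors = FALSE)
  qc <- unlist(lapply(verdicts, `[[`, "qc_flags"))
  live <- per[per$verdict != "discarded", , drop = FALSE]
  if (nrow(live) == 0L) {
    overall <- "rejected"
    qc <- c(qc, "insufficient valid reads")
  } else if (all(live$verdict == "positive")) {
    overall <- "brain_detected"
  } else if (all(live$verdict == "negative")) {
    overall <- "brain_not_detected"
  } else {
    overall <- "rejected"
    qc <- c(qc, "contradictory assay verdicts")
    pos_types <- unique(live$assay_type[live$verdict == "positive"])
    if (length(pos_types) == 1L) {
      other <- setdiff(c("hypo", "hyper"), pos_types)
      if (other %in% live$assay_type &&
          all(live$verdict[live$assay_type == other] == "negative"))
        qc <- c(qc, "possible bisulfite-efficiency artifact")
    }
  }
  structure(list(per_assay = per, overall = overall,
                 qc_flags = unique(qc)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus:", toupper(x$overall), "\n")
  print(x$per_assay, row.names = FALSE)
  for (f in x$qc_flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Assemble a per-assay diagnostic report
#'
#' One row per assay: name, amplicon length, type, held-out precision and
#' recall of the read-level tree, and CpG count.
#'
#' @param assays list of [amplicon_assay()] objects.
#' @param metrics list of `tree_metrics` aligned with `assays`.
#' @return A `data.frame` with columns `name`, `length_bp`, `type`,
#'   `precision`, `recall`, `n_cpg`.
#' @export
assay_report <- function(assays, metrics) {
  stopifnot(length(assays) == length(metrics))
  data.frame(
    name = vapply(assays, `[[`, "", "name"),
    length_bp = vapply(assays, function(a) as.integer(a$length_bp), integer(1)),
    type = vapply(assays, `[[`, "", "region_type"),
    precision = vapply(metrics, `[[`, 0, "precision"),
    recall = vapply(metrics, `[[`, 0, "recall"),
    n_cpg = vapply(assays, function(a) length(a$cpg_offsets), integer(1)),
    stringsAsFactors = FALSE)
}

#' Write verdicts and consensus artifacts
#'
#' @param report a `consensus_report`.
#' @param verdicts_path output TSV of per-assay verdicts.
#' @param consensus_path optional output JSON of the consensus.
#' @return `verdicts_path`, invisibly.
#' @export
write_consensus <- function(report, verdicts_path, consensus_path = NULL) {
  write.table(report$per_assay, verdicts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(consensus_path))
    jsonlite::write_json(list(overall = report$overall,
                              qc_flags = report$qc_flags,
                              per_assay = report$per_assay),
                         consensus_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(verdicts_path)
}
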