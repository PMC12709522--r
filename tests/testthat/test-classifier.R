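test_that("threshold verdicts follow the passing-fraction rule", {
  cfg <- classifier_config()
  # hyper assay with 60% of reads above 0.9 -> positive
  pct <- c(rep(0.95, 60), rep(0.3, 40))
  v <- classify_sample(pct, "hyper", cfg)
  expect_equal(v$verdict, "positive")
  expect_equal(v$passing_fraction, 0.6)

  # hypo assay, 4.9% passing -> negative; exactly 5% -> positive
  pct <- c(rep(0.05, 49), rep(0.5, 951))
  expect_equal(classify_sample(pct, "hypo", cfg)$verdict, "negative")
  pct <- c(rep(0.05, 50), rep(0.5, 950))
  expect_equal(classify_sample(pct, "hypo", cfg)$verdict, "positive")

  # read thresholds are inclusive
  expect_equal(classify_sample(rep(0.1, 10), "hypo", cfg)$passing_fraction, 1)
  expect_equal(classify_sample(rep(0.9, 10), "hyper", cfg)$passing_fraction, 1)

  # zero valid reads: discarded with flagged 0
  v0 <- classify_sample(numeric(0), "hypo", cfg)
  expect_equal(v0$verdict, "discarded")
  expect_equal(v0$passing_fraction, 0)
  expect_gt(length(v0$qc_flags), 0)

  # verdict is monotone in passing fraction
  verdicts <- vapply(seq(0, 0.2, 0.01), function(p) {
    n_pass <- round(p * 100)
    classify_sample(c(rep(0, n_pass), rep(0.5, 100 - n_pass)),
                    "hypo", cfg)$verdict
  }, "")
  expect_true(!is.unsorted(verdicts == "positive"))
})

test_that("a discarded read set is never called positive", {
  a <- tiny_assay()
  good <- build_read(a, rep(TRUE, 3))
  f <- tempfile(fileext = ".fastq")
  write_test_fastq(rep(good, 20), f)
  rs <- process_sample(f, NULL, a, caller_config(min_valid_reads = 100), "s")
  v <- classify_sample(rs, "hyper")
  expect_equal(v$verdict, "discarded")
  expect_equal(v$assay_name, "tiny")
})

test_that("decision tree on separable pools matches the percent baseline", {
  set.seed(77)
  n <- 600; k <- 8
  # fully disjoint epialleles: a single CpG separates the classes, so both
  # the depth-limited tree and the percent threshold are perfect
  brain <- matrix(0L, nrow = n, ncol = k)
  decoy <- matrix(1L, nrow = n, ncol = k)
  tm <- train_read_classifier(rbind(brain, decoy),
                              rep(c("brain", "non_brain"), each = n))
  expect_equal(tm$precision, 1)
  expect_equal(tm$recall, 1)
  expect_equal(tm$baseline_precision, 1)
  expect_equal(tm$baseline_recall, 1)
  expect_false(tm$tree_improves)
  expect_equal(tm$n_test, round(2 * n * 0.2))

  expect_error(train_read_classifier(brain, rep("brain", n)), "both classes")
})

test_that("held-out metrics reproduce hand-computed confusion counts", {
  # single informative CpG; the tree must split on it, making held-out
  # predictions (and thus the confusion matrix) fully determined
  n <- 50
  states <- cbind(c(rep(0, n), rep(1, n)), 0)
  labels <- rep(c("brain", "non_brain"), each = n)
  # corrupt 10 non-brain reads to look like brain
  states[n + 1:10, 1] <- 0
  cfg <- classifier_config(seed = 5)
  tm <- train_read_classifier(states, labels, cfg)
  # expected confusion on the held-out split, recomputed by hand here
  test_idx <- local({
    set.seed(cfg$seed)
    f <- factor(labels, levels = c("brain", "non_brain"))
    unlist(lapply(split(seq_along(labels), f), function(ix)
      sample(ix, round(length(ix) * cfg$test_fraction))))
  })
  pred_brain <- states[test_idx, 1] == 0
  truth_brain <- labels[test_idx] == "brain"
  tp <- sum(pred_brain & truth_brain)
  fp <- sum(pred_brain & !truth_brain)
  fn <- sum(!pred_brain & truth_brain)
  expect_equal(tm$precision, tp / (tp + fp))
  expect_equal(tm$recall, tp / (tp + fn))
})

test_that("resampling detection: endpoints, expectation, monotonicity", {
  cfg <- classifier_config(resample_reads = 2000, seed = 42)
  brain <- c(rep(0, 700), rep(0.6, 300))   # 70% passing on hypo
  decoy <- rep(0.8, 1000)                  # 0% passing

  expect_equal(simulate_detection(brain, decoy, 0, 20, "hypo", cfg), 0)
  expect_equal(simulate_detection(brain, decoy, 1, 20, "hypo", cfg), 1)
  expect_error(simulate_detection(brain, decoy, 0.5, 0, "hypo", cfg), "reps")
  expect_error(simulate_detection(numeric(0), decoy, 0.5, 5, "hypo", cfg))

  # same seed, same answer
  expect_equal(simulate_detection(brain, decoy, 0.08, 20, "hypo", cfg),
               simulate_detection(brain, decoy, 0.08, 20, "hypo", cfg))

  # mean passing fraction across replicates tracks f * r_b + (1-f) * r_d
  f <- 0.3
  r_b <- mean(brain <= 0.1); r_d <- mean(decoy <= 0.1)
  reps <- 200
  pf <- local({
    set.seed(7)
    vapply(seq_len(reps), function(i) {
      nb <- rbinom(1, 2000, f)
      draws <- c(sample(brain, nb, TRUE), sample(decoy, 2000 - nb, TRUE))
      classify_sample(draws, "hypo", cfg)$passing_fraction
    }, 0)
  })
  expected <- f * r_b + (1 - f) * r_d
  se <- sd(pf) / sqrt(reps)
  expect_lt(abs(mean(pf) - expected), 3 * se + 1e-6)

  # detection rate is non-decreasing in f (Monte-Carlo tolerance 0.02)
  rates <- vapply(c(0, 0.02, 0.05, 0.1, 0.3, 1), function(fr)
    simulate_detection(brain, decoy, fr, 40, "hypo", cfg), 0)
  expect_true(all(diff(rates) >= -0.02))
})

test_that("consensus: unanimity, contradiction, bisulfite flag, discards", {
  mk <- function(assay, type, verdict)
    structure(list(sample_id = "s", assay_name = assay, assay_type = type,
                   n_valid = 1000L,
                   passing_fraction = if (verdict == "positive") 0.5 else 0.01,
                   verdict = verdict, qc_flags = character(0)),
              class = "sample_verdict")
  four <- function(v1, v2, v3, v4)
    list(mk("n7", "hyper", v1), mk("n8", "hyper", v2),
         mk("n11", "hypo", v3), mk("n13", "hypo", v4))

  r <- consensus_verdict(four("positive", "positive", "positive", "positive"))
  expect_equal(r$overall, "brain_detected")
  r <- consensus_verdict(four("negative", "negative", "negative", "negative"))
  expect_equal(r$overall, "brain_not_detected")

  # hypo positive, hyper negative: rejected, bisulfite artifact flagged
  r <- consensus_verdict(four("negative", "negative", "positive", "positive"))
  expect_equal(r$overall, "rejected")
  expect_true(any(grepl("contradictory", r$qc_flags)))
  expect_true(any(grepl("bisulfite", r$qc_flags)))

  # mixed within a type: rejected without the bisulfite flag
  r <- consensus_verdict(four("positive", "negative", "positive", "negative"))
  expect_equal(r$overall, "rejected")
  expect_false(any(grepl("bisulfite", r$qc_flags)))

  # discarded assays are ignored; all discarded rejects outright
  vs <- four("positive", "positive", "positive", "positive")
  vs[[1]]$verdict <- "discarded"
  expect_equal(consensus_verdict(vs)$overall, "brain_detected")
  vs <- lapply(vs, function(v) { v$verdict <- "discarded"; v })
  r <- consensus_verdict(vs)
  expect_equal(r$overall, "rejected")
  expect_true(any(grepl("insufficient", r$qc_flags)))
})

test_that("assay report has the diagnostic-table shape", {
  set.seed(15)
  panel <- synthetic_assay_panel()
  metrics <- lapply(panel, function(a) {
    k <- length(a$cpg_offsets)
    n <- 200
    p_brain <- if (a$region_type == "hypo") 0.05 else 0.95
    states <- rbind(matrix(rbinom(n * k, 1, p_brain), nrow = n),
                    matrix(rbinom(n * k, 1, 1 - p_brain), nrow = n))
    train_read_classifier(states, rep(c("brain", "non_brain"), each = n))
  })
  rep <- assay_report(panel, metrics)
  expect_equal(names(rep),
               c("name", "length_bp", "type", "precision", "recall", "n_cpg"))
  expect_equal(rep$name, c("n7", "n8", "n11", "n13"))
  expect_equal(rep$length_bp, c(268L, 204L, 111L, 210L))
  expect_true(all(rep$precision >= 0 & rep$precision <= 1))
  expect_true(all(rep$recall >= 0 & rep$recall <= 1))
  f <- tempfile(fileext = ".tsv")
  write_assay_report(rep, f)
  expect_equal(nrow(read.table(f, header = TRUE, sep = "\t")), 4L)
})
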