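test_that("pair merging: overlap detection, bounds, quality resolution", {
  set.seed(21)
  base <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  r1 <- substr(base, 1, 150)
  r2 <- revcomp_str(substr(base, 101, 250))  # 50-bp exact overlap
  m <- merge_pair(r1, r2)
  expect_equal(nchar(m$seq), 250)
  expect_equal(m$seq, base)
  expect_equal(m$overlap, 50)
  expect_equal(m$agreement, 1)

  # identical reads fully overlap and merge to themselves
  m <- merge_pair(r1, revcomp_str(r1))
  expect_equal(m$seq, r1)
  expect_equal(m$overlap, 150)

  # 10-bp overlap is below the minimum
  short <- paste(sample(c("A", "C", "G", "T"), 290, TRUE), collapse = "")
  expect_null(merge_pair(substr(short, 1, 150),
                         revcomp_str(substr(short, 141, 290))))

  # disagreement resolved by quality, tie to R1
  r1 <- "ACGTACGTACGTACGTACGTAAAA"
  r2_t <- "ACGTACGTACGTACGTACGTAAAT"  # last base differs
  r2 <- revcomp_str(r2_t)
  cfg <- caller_config(merge_min_overlap = 10, merge_min_agreement = 0.8)
  hiq <- strrep("I", 24); loq <- strrep("#", 24)
  expect_equal(substr(merge_pair(r1, r2, hiq, loq, cfg)$seq, 24, 24), "A")
  expect_equal(substr(merge_pair(r1, r2, loq, hiq, cfg)$seq, 24, 24), "T")
  expect_equal(substr(merge_pair(r1, r2, hiq, hiq, cfg)$seq, 24, 24), "A")
})

test_that("alignment identity excludes CpG cytosines from both sides", {
  panel <- synthetic_assay_panel()
  a <- panel$n8  # 204 bp, 23 CpGs
  k <- length(a$cpg_offsets)
  L <- a$length_bp
  read <- build_read(a, rep(FALSE, k))
  cl <- call_read(read, NULL, a)
  expect_true(cl$valid)
  expect_equal(cl$identity, 1)
  expect_equal(cl$methylation_percent, 0)

  # substitutions only at CpG cytosines leave identity at 1
  states <- rep(c(TRUE, FALSE), length.out = k)
  cl <- call_read(build_read(a, states), NULL, a)
  expect_equal(cl$identity, 1)
  expect_equal(cl$methylation_percent, mean(states))

  # 10 substitutions at non-CpG, non-primer positions; prohibitive gap
  # penalties keep the alignment ungapped so the counting oracle applies
  # (the converted, T-rich sequence is repetitive enough that cheap gaps
  # could otherwise re-match a flipped base)
  x <- strsplit(read, "")[[1]]
  excluded <- c(a$cpg_offsets, a$cpg_offsets + 1L, seq_len(21),
                (L - 20):L)
  targets <- setdiff(seq_len(L), excluded)[1:10]
  x[targets] <- ifelse(x[targets] == "A", "G", "A")
  cfg <- caller_config(align_gap_open = -50, align_gap_extend = -50)
  cl <- call_read(paste(x, collapse = ""), NULL, a, cfg)
  expect_equal(cl$identity, (L - k - 10) / (L - k), tolerance = 1e-12)
})

test_that("filters fire in order with a single rejection reason each", {
  a <- tiny_assay()
  k <- length(a$cpg_offsets)
  good <- build_read(a, rep(TRUE, k))

  cl <- call_read(good, NULL, a)
  expect_true(cl$valid)
  expect_equal(cl$methylation_percent, 1)
  expect_equal(cl$rejection_reason, "none")

  # primer mismatch beats everything else
  bad_primer <- paste0("G", substr(good, 2, nchar(good)))
  expect_equal(call_read(bad_primer, NULL, a)$rejection_reason,
               "primer_mismatch")

  # truncated read misses the last CpG
  trunc <- substr(good, 1, max(a$cpg_offsets) - 2)
  expect_equal(call_read(trunc, NULL, a)$rejection_reason,
               "incomplete_cpg_coverage")

  # shredding the non-CpG interior drops identity below 0.85
  x <- strsplit(good, "")[[1]]
  idx <- setdiff(9:(nchar(good) - 8), c(a$cpg_offsets, a$cpg_offsets + 1L))
  x[idx] <- ifelse(x[idx] == "A", "G", "A")
  expect_equal(call_read(paste(x, collapse = ""), NULL, a)$rejection_reason,
               "low_identity")

  # a CpG reading AG is neither CG nor TG
  x <- strsplit(good, "")[[1]]
  x[a$cpg_offsets[2]] <- "A"
  expect_equal(call_read(paste(x, collapse = ""), NULL, a)$rejection_reason,
               "invalid_cpg_state")

  # unmergeable pair: R2 from unrelated sequence
  set.seed(31)
  alien <- paste(sample(c("A", "G", "T"), nchar(good), TRUE), collapse = "")
  expect_equal(call_read(good, alien, a,
                         caller_config())$rejection_reason,
               "unmergeable_pair")
})

test_that("strict literal CG/CT mode is available behind a flag", {
  a <- tiny_assay()
  k <- length(a$cpg_offsets)
  # chemistry-consistent unmethylated read (TG at CpGs) fails literal mode
  tg_read <- build_read(a, rep(FALSE, k))
  strict <- caller_config(strict_literal_ct = TRUE)
  expect_equal(call_read(tg_read, NULL, a, strict)$rejection_reason,
               "invalid_cpg_state")
  # literal-CT read: C retained, G -> T after the CpG
  x <- strsplit(build_read(a, rep(TRUE, k)), "")[[1]]
  x[a$cpg_offsets + 1L] <- "T"
  ct_read <- paste(x, collapse = "")
  cl <- call_read(ct_read, NULL, a, strict)
  expect_true(cl$valid)
  expect_equal(cl$methylation_percent, 0)  # CT = unmethylated, literally
})

test_that("gapped reads are aligned and recover CpG states", {
  panel <- synthetic_assay_panel()
  a <- panel$n13
  k <- length(a$cpg_offsets)
  states <- rep(c(TRUE, FALSE), length.out = k)
  read <- build_read(a, states)
  # delete one base between the 2nd and 3rd CpG (non-CpG position)
  del_at <- a$cpg_offsets[2] + 3L
  gapped <- paste0(substr(read, 1, del_at - 1),
                   substr(read, del_at + 1, nchar(read)))
  cl <- call_read(gapped, NULL, a)
  expect_true(cl$valid)
  expect_equal(cl$methylation_percent, mean(states))
  expect_lt(cl$identity, 1)
})

test_that("sample processing: accounting, discard boundary, order invariance", {
  a <- tiny_assay()
  k <- length(a$cpg_offsets)
  cfg <- caller_config(min_valid_reads = 100)
  good <- build_read(a, rep(TRUE, k))
  bad <- paste0("G", substr(good, 2, nchar(good)))

  f <- tempfile(fileext = ".fastq")
  # 99 valid + 30 rejected -> discarded
  write_test_fastq(c(rep(good, 99), rep(bad, 30)), f)
  rs <- process_sample(f, NULL, a, cfg, "s1")
  expect_true(rs$discarded)
  expect_equal(nrow(rs$valid_calls), 99L)
  expect_equal(sum(rs$rejection_counts), 30L)
  expect_equal(nrow(rs$valid_calls) + sum(rs$rejection_counts), rs$n_total)

  # exactly 100 valid reads is not fewer than 100
  write_test_fastq(rep(good, 100), f)
  expect_false(process_sample(f, NULL, a, cfg, "s1")$discarded)

  # zero input reads
  write_test_fastq(character(0), f)
  rs0 <- process_sample(f, NULL, a, cfg, "s1")
  expect_true(rs0$discarded)
  expect_equal(rs0$n_total, 0L)

  # shuffling read order changes no counts
  set.seed(13)
  mix <- sample(c(rep(good, 40), rep(bad, 15)))
  write_test_fastq(mix, f)
  rs1 <- process_sample(f, NULL, a, cfg, "s1")
  write_test_fastq(rev(mix), f)
  rs2 <- process_sample(f, NULL, a, cfg, "s1")
  expect_equal(rs1$rejection_counts, rs2$rejection_counts)
  expect_equal(nrow(rs1$valid_calls), nrow(rs2$valid_calls))

  # mismatched R1/R2 record counts
  f2 <- tempfile(fileext = ".fastq")
  write_test_fastq(rep(good, 3), f)
  write_test_fastq(rep(good, 2), f2)
  expect_error(process_sample(f, f2, a, cfg, "s1"), "record counts")
})

test_that("read call output writers produce parseable artifacts", {
  a <- tiny_assay()
  good <- build_read(a, c(TRUE, FALSE, TRUE))
  f <- tempfile(fileext = ".fastq")
  write_test_fastq(rep(good, 5), f)
  rs <- process_sample(f, NULL, a, caller_config(min_valid_reads = 1), "s1")
  calls <- tempfile(fileext = ".tsv"); summ <- tempfile(fileext = ".json")
  write_read_calls(rs, calls, summ)
  tab <- read.table(calls, header = TRUE, sep = "\t",
                    colClasses = c(pattern = "character"))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$pattern[1], "101")
  js <- jsonlite::read_json(summ)
  expect_equal(js$n_valid, 5L)
  expect_false(js$discarded)
})
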