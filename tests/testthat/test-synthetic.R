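test_that("molecule sampling follows archetype weights and probabilities", {
  a <- synthetic_assay_panel()$n13
  k <- length(a$cpg_offsets)
  set.seed(2)
  all1 <- sample_molecule(tissue_profile("x", "t", 1, list(rep(1, k))), 50)
  expect_true(all(all1$patterns))
  all0 <- sample_molecule(tissue_profile("x", "t", 1, list(rep(0, k))), 50)
  expect_false(any(all0$patterns))

  n <- 4000
  prof <- brain_profile(a)  # weights (0.9, 0.1)
  mol <- sample_molecule(prof, n)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(mean(mol$archetype == 1) - 0.9), 3 * se)
  # per-CpG methylation of archetype-1 molecules near 0.03
  m1 <- mol$patterns[mol$archetype == 1, ]
  se1 <- sqrt(0.03 * 0.97 / length(m1))
  expect_lt(abs(mean(m1) - 0.03), 3 * se1)
})

test_that("read generation is byte-deterministic and well-formed", {
  a <- synthetic_assay_panel()$n11
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generate_reads(brain_profile(a), a, 200, noise_model(), seed = 9,
                       out_dir = d1, prefix = "x")
  g2 <- generate_reads(brain_profile(a), a, 200, noise_model(), seed = 9,
                       out_dir = d2, prefix = "x")
  expect_identical(readLines(g1$paths$r1), readLines(g2$paths$r1))
  expect_identical(readLines(g1$paths$r2), readLines(g2$paths$r2))
  g3 <- generate_reads(brain_profile(a), a, 200, noise_model(), seed = 10,
                       out_dir = d2, prefix = "y")
  expect_false(identical(readLines(g1$paths$r1), readLines(g3$paths$r1)))

  # 4-line records, quality length equals sequence length
  lines <- readLines(g1$paths$r1)
  expect_equal(length(lines) %% 4, 0)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_equal(nchar(lines[seq(2, length(lines), 4)]),
               nchar(lines[seq(4, length(lines), 4)]))
  # amplicon shorter than the read length: reads cover the full insert
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == a$length_bp))

  # the effective configuration is serialized alongside the output
  cfgf <- yaml::read_yaml(g1$paths$config)
  expect_equal(cfgf$seed, 9)
  expect_equal(cfgf$n, 200)
})

test_that("noiseless reads round-trip through the caller exactly", {
  a <- synthetic_assay_panel()$n8
  g <- generate_reads(brain_profile(a), a, 300, noise_model(1, 0, 0),
                      seed = 4, out_dir = tempfile(), prefix = "rt")
  rs <- process_sample(g$paths$r1, g$paths$r2, a, caller_config(), "s")
  expect_equal(nrow(rs$valid_calls), 300L)
  expect_identical(rs$valid_calls$pattern, g$truth$pattern)
  expect_equal(rs$valid_calls$methylation_percent,
               g$truth$methylation_percent)
})

test_that("recovered methylation under default noise matches the profile", {
  a <- synthetic_assay_panel()$n13
  k <- length(a$cpg_offsets)
  prof <- decoy_profile(a)  # homogeneous per-CpG probability 0.9
  g <- generate_reads(prof, a, 1500, noise_model(), seed = 6,
                      out_dir = tempfile(), prefix = "dec")
  rs <- process_sample(g$paths$r1, g$paths$r2, a, caller_config(), "s")
  expect_gt(nrow(rs$valid_calls), 1000)
  # conversion errors shift the per-CpG expectation slightly:
  # P(read C) = p(1 - phi) + (1 - p)(1 - eta)
  nm <- noise_model()
  p <- 0.9
  exp_c <- p * (1 - nm$inappropriate_conversion) +
    (1 - p) * (1 - nm$conversion_efficiency)
  n_states <- nrow(rs$valid_calls) * k
  se <- sqrt(exp_c * (1 - exp_c) / n_states)
  expect_lt(abs(mean(rs$valid_calls$methylation_percent) - exp_c), 3 * se)
})

test_that("mixtures resample components at their weights with provenance", {
  a <- synthetic_assay_panel()$n11
  dir <- tempfile()
  gb <- generate_reads(brain_profile(a), a, 800, noise_model(1, 0, 0),
                       seed = 1, out_dir = dir, prefix = "b")
  gd <- generate_reads(decoy_profile(a), a, 800, noise_model(1, 0, 0),
                       seed = 2, out_dir = dir, prefix = "d")
  n <- 4000
  mx <- mix_read_sets(list(
    list(r1 = gb$paths$r1, r2 = gb$paths$r2, weight = 0.1),
    list(r1 = gd$paths$r1, r2 = gd$paths$r2, weight = 0.9)),
    n_total = n, seed = 3, out_dir = dir, prefix = "m")
  ids <- sub("\\s.*$", "", names(Biostrings::readDNAStringSet(
    mx$paths$r1, format = "fastq")))
  n_brain <- sum(grepl("src=1", ids))
  se <- sqrt(0.1 * 0.9 * n)
  expect_lt(abs(n_brain - 0.1 * n), 3 * se)
  expect_equal(length(ids), n)

  # single component: a straight resample
  mx1 <- mix_read_sets(list(list(r1 = gb$paths$r1, r2 = gb$paths$r2,
                                 weight = 1)), 500, seed = 4,
                       out_dir = dir, prefix = "m1")
  expect_true(all(mx1$source == 1))
  expect_error(mix_read_sets(list(list(r1 = gb$paths$r1, r2 = gb$paths$r2,
                                       weight = 0.5)), 10), "sum to 1")
})

test_that("degradation: identity settings, truncation, depth loss", {
  a <- synthetic_assay_panel()$n13
  dir <- tempfile()
  g <- generate_reads(brain_profile(a), a, 1000, noise_model(1, 0, 0),
                      seed = 5, out_dir = dir, prefix = "src")

  # depth 1, no truncation, multiplier 1: the identity transform
  dg <- apply_degradation(g$paths$r1, g$paths$r2,
                          degradation_spec(1, 0, 1), seed = 6,
                          out_dir = dir, prefix = "id", assay = a)
  expect_equal(dg$n_kept, 1000L)
  r_in <- as.character(Biostrings::readDNAStringSet(g$paths$r1, format = "fastq"))
  r_out <- as.character(Biostrings::readDNAStringSet(dg$paths$r1, format = "fastq"))
  expect_equal(unname(r_out), unname(r_in))

  # full truncation: every kept pair fails CpG coverage downstream
  dg <- apply_degradation(g$paths$r1, g$paths$r2,
                          degradation_spec(0.5, 0.999, 1), seed = 7,
                          out_dir = dir, prefix = "tr", assay = a)
  rs <- process_sample(dg$paths$r1, dg$paths$r2, a, caller_config(), "s")
  expect_equal(nrow(rs$valid_calls), 0L)
  expect_equal(sum(rs$rejection_counts[c("incomplete_cpg_coverage",
                                         "unmergeable_pair")]),
               rs$n_total)

  # depth loss is binomial around depth_factor * n
  dg <- apply_degradation(g$paths$r1, g$paths$r2,
                          degradation_spec(0.3, 0, 1), seed = 8,
                          out_dir = dir, prefix = "dp", assay = a)
  se <- sqrt(0.3 * 0.7 * 1000)
  expect_lt(abs(dg$n_kept - 300), 3 * se)
})

test_that("synthetic compendia plant recoverable regions and only those", {
  dir <- tempfile()
  spec <- compendium_sim_spec(
    n_positions = 150,
    planted_regions = list(list(start_index = 60, n_cpg = 8, mode = "hypo",
                                brain_level = 0.02, decoy_level = 0.95)),
    seed = 17)
  out <- generate_compendium(spec, out_dir = dir)
  # determinism: same spec, same table content (paths differ by directory)
  out2 <- generate_compendium(spec, out_dir = tempfile())
  b1 <- readLines(file.path(dir, "brain01.bedgraph"))
  b2 <- readLines(file.path(dirname(out2$manifest), "brain01.bedgraph"))
  expect_identical(b1, b2)

  comp <- build_compendium(out$manifest)
  reg <- rank_regions(find_candidate_regions(score_compendium(comp)))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$region_type, "hypo")
  t <- out$truth_regions
  inter <- max(0, min(reg$end[1], t$end) - max(reg$start[1], t$start))
  jacc <- inter / (max(reg$end[1], t$end) - min(reg$start[1], t$start))
  expect_gte(jacc, 0.5)

  # hyper planting is recovered with the right direction
  spec2 <- compendium_sim_spec(
    n_positions = 150,
    planted_regions = list(list(start_index = 40, n_cpg = 6, mode = "hyper",
                                brain_level = 0.97, decoy_level = 0.05)),
    seed = 18)
  out3 <- generate_compendium(spec2, out_dir = tempfile())
  reg3 <- rank_regions(find_candidate_regions(score_compendium(
    build_compendium(out3$manifest))))
  expect_equal(reg3$region_type[1], "hyper")

  # planted-region validation
  expect_error(compendium_sim_spec(n_positions = 50, planted_regions =
    list(list(start_index = 48, n_cpg = 8))), "out of range")
  expect_error(compendium_sim_spec(planted_regions =
    list(list(start_index = 10, n_cpg = 4))), "at least 5")

  # decoy dropout produces missing entries that the compendium tolerates
  spec3 <- compendium_sim_spec(n_positions = 80, decoy_missing_rate = 0.1,
                               seed = 19)
  out4 <- generate_compendium(spec3, out_dir = tempfile())
  comp4 <- build_compendium(out4$manifest)
  expect_gt(sum(is.na(comp4$values)), 0)
  expect_true(all(comp4$values >= 0 & comp4$values <= 1, na.rm = TRUE))
})
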