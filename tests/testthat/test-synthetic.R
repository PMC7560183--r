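test_that("generators are deterministic under a fixed seed", {
  a <- simulate_genome_pair(c(chrT1 = 40000L), seed = 121)
  b <- simulate_genome_pair(c(chrT1 = 40000L), seed = 121)
  expect_identical(unclass(a$template), unclass(b$template))
  expect_identical(unclass(a$target), unclass(b$target))
  expect_identical(a$truth, b$truth)
  g <- random_genome(c(chr1 = 50000), seed = 122)
  expect_identical(simulate_probes(g, spacing = 5000, seed = 123),
                   simulate_probes(g, spacing = 5000, seed = 123))
  s1 <- simulate_sex_mismatch(x_length = 1e7, autosome_lengths = NULL,
                              par_length = 5e6, seed = 124)
  s2 <- simulate_sex_mismatch(x_length = 1e7, autosome_lengths = NULL,
                              par_length = 5e6, seed = 124)
  expect_identical(s1$track, s2$track)
})

test_that("zero divergence reproduces the template as scaffolds", {
  sim <- simulate_genome_pair(c(chrT1 = 40000L), locus_length = 2000L,
                              substitution_rate = 0, indel_rate = 0,
                              deleted_fraction = 0, duplicated_fraction = 0,
                              seed = 125)
  truth <- sim$truth
  expect_true(all(truth$status == "orthologous"))
  for (i in seq_len(nrow(truth))) {
    expect_identical(sim$target[[truth$scaffold[i]]],
                     get_subsequence(sim$template, truth$chrom[i],
                                     truth$start[i], truth$end[i]))
  }
})

test_that("deleted and duplicated locus counts are exact", {
  sim <- simulate_genome_pair(c(chrT1 = 200000L), locus_length = 2000L,
                              deleted_fraction = 0.3,
                              duplicated_fraction = 0.1, seed = 126)
  expect_equal(sum(sim$truth$status == "deleted"), 30)
  expect_equal(sum(sim$truth$status == "duplicated"), 10)
  dup <- sim$truth[sim$truth$status == "duplicated", ]
  expect_identical(sim$target[[dup$scaffold[1]]], sim$target[[dup$scaffold2[1]]])
  expect_true(all(is.na(sim$truth$scaffold[sim$truth$status == "deleted"])))
})

test_that("realized substitution counts match the truth labels when diffing", {
  sim <- simulate_genome_pair(c(chrT1 = 60000L), locus_length = 2000L,
                              substitution_rate = 0.04, indel_rate = 0,
                              deleted_fraction = 0, duplicated_fraction = 0,
                              seed = 127)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    tpl <- strsplit(get_subsequence(sim$template, truth$chrom[i],
                                    truth$start[i], truth$end[i]), "")[[1]]
    tgt <- strsplit(sim$target[[truth$scaffold[i]]], "")[[1]]
    expect_equal(sum(tpl != tgt), truth$n_sub[i])
  }
})

test_that("simulated probes hit the target spacing and are clean", {
  g <- random_genome(c(chr1 = 1e6), seed = 128)
  p <- simulate_probes(g, spacing = 20000, seed = 129)
  expect_gt(nrow(p), 40)
  expect_lt(nrow(p), 60)
  expect_false(any(grepl("N", p$sequence)))
  expect_true(all(diff(p$start) >= nchar(p$sequence[1])))  # non-overlapping
  s <- spacing_summary(p$start, 1e6, "chr1")
  expect_lt(abs(s$mean_spacing - 20000) / 20000, 0.1)
})

test_that("noise-free CGH tracks equal the truth and recover breakpoints", {
  probes <- data.frame(id = sprintf("p%03d", 1:100), chrom = "A1",
                       pos = (0:99) * 2e4)
  cna <- data.frame(chrom = "A1", start = 6e5, end = 1e6, log2 = 0.5)
  tr <- simulate_cgh(probes, cna, noise_sd = 0, seed = 130)
  expect_equal(tr$log2, tr$truth_log2)
  seg <- segment_track(tr)
  expect_equal(seg$start[2], 6e5)
  expect_equal(seg$start[3], 1e6)
  # sampling-theory check at sd 0.15: per-segment mean within 3 SE of truth
  trn <- simulate_cgh(probes, cna, noise_sd = 0.15, seed = 131)
  for (lev in unique(trn$truth_log2)) {
    v <- trn$log2[trn$truth_log2 == lev]
    expect_lt(abs(mean(v) - lev), 3 * 0.15 / sqrt(length(v)))
  }
})

test_that("sex-mismatch tracks carry the recorded PAR truth", {
  sim <- simulate_sex_mismatch(x_length = 1.5e7, par_length = 7e6,
                               autosome_lengths = c(A1 = 5e6),
                               noise_sd = 0, seed = 132)
  b <- detect_par_boundary(sim$track)
  expect_equal(b$last_balanced_pos, sim$truth$last_par_pos)
  expect_equal(b$first_unbalanced_pos, sim$truth$first_x_pos)
  # an embedded 3-probe autosomal loss is recovered
  sim2 <- simulate_sex_mismatch(x_length = 1.5e7, par_length = 7e6,
                                autosome_lengths = c(A3 = 2e7),
                                spacing = 16000,
                                cna = data.frame(chrom = "A3", start = 3.2e6,
                                                 end = 3.264e6, log2 = -1.5),
                                noise_sd = 0, seed = 133)
  regs <- find_discordant_autosomal_regions(sim2$track)
  expect_equal(nrow(regs), 1)
  expect_identical(regs$state, "high_loss")
  expect_gte(regs$n_probes, 3)
})
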