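make_template <- function(len = 10000, seed = 61) {
  genome_assembly(c(chrT = rand_seq(len, seed = seed)), name = "template")
}

test_that("probe extension adds clipped flanks and tracks the core offset", {
  g <- make_template()
  p <- list(chrom = "chrT", start = 1000L, end = 1060L)
  ext <- extend_probe(p, g, flank = 100)
  expect_equal(ext$start, 900)
  expect_equal(ext$end, 1160)
  expect_equal(nchar(ext$sequence), 260)
  expect_equal(ext$core_offset, 100)
  # substring oracle on the raw genome string
  expect_identical(ext$sequence, substr(g[["chrT"]], 901, 1160))
  expect_identical(substr(ext$sequence, 101, 160),
                   get_subsequence(g, "chrT", 1000, 1060))
  # boundary clipping
  ext2 <- extend_probe(list(chrom = "chrT", start = 30L, end = 90L), g, 100)
  expect_equal(ext2$start, 0)
  expect_equal(ext2$core_offset, 30)
})

test_that("ortholog search distinguishes hits, absences, and ambiguity", {
  g <- make_template()
  ext <- extend_probe(list(chrom = "chrT", start = 5000L, end = 5060L), g, 100)
  # target identical to template: identity-1 hit at the source locus
  fo <- find_ortholog(ext$sequence, g)
  expect_identical(fo$status, "hit")
  expect_equal(fo$hit$identity, 1.0)
  expect_equal(fo$hit$sstart, 4901)
  # 5% substitution divergence: still located at the planted position
  set.seed(62)
  tgt <- genome_assembly(c(s1 = plant_seq(rand_seq(3000),
                                          mutate_seq(ext$sequence, 0.05), 1201)))
  fo2 <- find_ortholog(ext$sequence, tgt)
  expect_identical(fo2$status, "hit")
  expect_equal(fo2$hit$sstart, 1201, tolerance = 3)
  # verbatim duplication on two scaffolds is ambiguous
  dup <- genome_assembly(c(s1 = plant_seq(rand_seq(1000), ext$sequence, 400),
                           s2 = plant_seq(rand_seq(1000), ext$sequence, 100)))
  fo3 <- find_ortholog(ext$sequence, dup)
  expect_identical(fo3$status, "ambiguous_map")
  # unrelated target: no alignment
  set.seed(63)
  fo4 <- find_ortholog(ext$sequence, genome_assembly(c(s1 = rand_seq(2000))))
  expect_identical(fo4$status, "no_alignment")
  expect_error(find_ortholog(ext$sequence, character(0)), "empty")
})

test_that("core extraction replays the aligned-column map", {
  g <- make_template()
  ext <- extend_probe(list(chrom = "chrT", start = 4000L, end = 4060L), g, 100)
  # gap-free: the co-linear 60-mer
  fo <- find_ortholog(ext$sequence, g)
  core <- extract_core(fo$hit, ext$core_offset, ext$core_length)
  expect_identical(core$status, "ok")
  expect_equal(core$start, 4000)
  expect_equal(core$end, 4060)
  # a 3-nt deletion inside the core shrinks the extracted interval to 57 nt
  seq60 <- get_subsequence(g, "chrT", 4000, 4060)
  del <- paste0(substr(ext$sequence, 1, 125), substr(ext$sequence, 129, 260))
  tgt <- genome_assembly(c(s1 = plant_seq(rand_seq(1000, seed = 64), del, 301)))
  fo2 <- find_ortholog(ext$sequence, tgt)
  core2 <- extract_core(fo2$hit, ext$core_offset, ext$core_length)
  expect_identical(core2$status, "ok")
  expect_equal(core2$end - core2$start, 57)
  # per-column replay oracle: the extracted interval spans exactly the
  # subject positions aligned to core columns
  hit <- fo2$hit
  lo <- ext$core_offset + 1; hi <- ext$core_offset + ext$core_length
  sel <- hit$qmap >= lo & hit$qmap <= hi
  expect_equal(core2$start, min(hit$smap[sel]) - 1)
  expect_equal(core2$end, max(hit$smap[sel]))
  # wholly unaligned core fails
  bad <- extract_core(list(qmap = 1:50, smap = 1:50, chrom = "s1"), 100, 60)
  expect_identical(bad$status, "unaligned")
})

test_that("uniqueness verification counts near-match loci", {
  set.seed(66)
  cand <- rand_seq(60)
  once <- genome_assembly(c(s1 = plant_seq(rand_seq(2000), cand, 700)))
  expect_identical(verify_unique(cand, once)$status, "unique")
  twice <- genome_assembly(c(s1 = plant_seq(rand_seq(2000), cand, 700),
                             s2 = plant_seq(rand_seq(1000), cand, 200)))
  expect_identical(verify_unique(cand, twice)$status, "ambiguous_map")
  # one exact and one 92%-identity copy (5 substitutions in 60) is ambiguous
  near <- mutate_seq(cand, 0, seed = 67)
  ch <- strsplit(near, "")[[1]]
  idx <- sample(60, 5)
  other <- list(A = "C", C = "G", G = "T", T = "A")
  for (i in idx) ch[i] <- other[[ch[i]]]
  near <- paste(ch, collapse = "")
  mixed <- genome_assembly(c(s1 = plant_seq(rand_seq(2000), cand, 700),
                             s2 = plant_seq(rand_seq(1000), near, 200)))
  expect_identical(verify_unique(cand, mixed)$status, "ambiguous_map")
  expect_equal(verify_unique(cand, mixed)$n_loci, 2)
})

test_that("identity migration yields all exact matches and a conserving ledger", {
  g <- make_template(len = 30000, seed = 68)
  p <- simulate_probes(g, spacing = 3000, seed = 69)
  res <- migrate_probes(p, g, g)
  expect_identical(unique(res$records$status), "exact_match")
  led <- res$ledger
  expect_equal(led$total, nrow(p))
  expect_equal(led$final, nrow(p))
  expect_equal(led$no_alignment + led$candidates + led$failed_adjust, led$total)
  # determinism: identical inputs yield byte-identical record tables
  res2 <- migrate_probes(p, g, g)
  expect_identical(res$records, res2$records)
})

test_that("migration statuses recover the synthetic truth labels", {
  sim <- simulate_genome_pair(chrom_lengths = c(chrT1 = 120000L),
                              locus_length = 2000L,
                              substitution_rate = 0.03, indel_rate = 0.001,
                              deleted_fraction = 0.1,
                              duplicated_fraction = 0.05, seed = 70)
  truth <- sim$truth
  # one probe centred in each template locus
  mid <- truth$start + 970L
  probes <- probe_set(sprintf("p%03d", seq_len(nrow(truth))), truth$chrom,
                      mid, mid + 60L, genome = sim$template)
  res <- migrate_probes(probes, sim$template, sim$target)
  rec <- res$records[match(probes$id, res$records$id), ]
  expected <- ifelse(truth$status == "deleted", "no_alignment",
                     ifelse(truth$status == "duplicated", "ambiguous_map",
                            "success"))
  got <- ifelse(rec$status %in% c("exact_match", "direct_ortholog", "adjusted"),
                "success", rec$status)
  expect_gte(mean(got == expected), 0.95)
  # every emitted probe is unique in the target and satisfies its tolerances
  succ <- res$records[res$records$status %in%
                        c("direct_ortholog", "adjusted"), ]
  th <- thermo_params()
  for (i in seq_len(nrow(succ))) {
    j <- match(succ$id[i], probes$id)
    expect_lte(abs(succ$tm[i] - probes$tm[j]), th$tm_tolerance)
    expect_lte(abs(succ$gc[i] - probes$gc[j]), th$gc_tolerance)
    expect_identical(verify_unique(succ$sequence[i], sim$target)$status,
                     "unique")
  }
})

test_that("migration records and ledger export as TSV", {
  g <- make_template(len = 10000, seed = 71)
  p <- simulate_probes(g, spacing = 2500, seed = 72)
  res <- migrate_probes(p, g, g)
  rf <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_migration(res, rf, lf)
  rec <- read.delim(rf)
  expect_equal(nrow(rec), nrow(p))
  expect_equal(rec$start, res$records$start + 1)  # printed 1-based
  led <- read.delim(lf)
  expect_true(all(c("total", "final") %in% led$stage))
})
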