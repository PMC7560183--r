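test_that("log2 ratios match the elementwise oracle and center on autosomes", {
  set.seed(91)
  n <- 50
  d <- data.frame(probe = sprintf("p%02d", 1:n),
                  chrom = rep(c("A1", "X"), each = 25),
                  pos = rep(seq(0, by = 1e4, length.out = 25), 2),
                  test = runif(n, 50, 500), reference = runif(n, 50, 500))
  raw <- compute_log2_ratios(d, normalization = "none")
  m <- match(raw$probe, d$probe)
  expect_equal(raw$log2, log2(d$test[m] / d$reference[m]))
  expect_equal(compute_log2_ratios(
    data.frame(probe = "p", chrom = "A1", pos = 0, test = 200, reference = 100),
    normalization = "none")$log2, 1.0)
  cen <- compute_log2_ratios(d, normalization = "median")
  expect_equal(median(cen$log2[cen$chrom == "A1"]), 0)
  # non-positive intensities are excluded, not errors
  d$test[3] <- 0
  expect_message(out <- compute_log2_ratios(d, normalization = "none"),
                 "non-positive")
  expect_equal(nrow(out), n - 1)
})

test_that("flagged probes are filtered with a count", {
  tr <- ratio_track(sprintf("p%02d", 1:10), "A1", (1:10) * 1e4, rnorm(10),
                    non_uniform = c(rep(FALSE, 8), TRUE, FALSE),
                    saturated = c(TRUE, rep(FALSE, 9)))
  expect_message(f <- filter_track(tr), "2 flagged")
  expect_equal(nrow(f), 8)
  clean <- ratio_track("p1", "A1", 0, 0.5)
  expect_identical(filter_track(clean)$probe, "p1")
  allbad <- ratio_track("p1", "A1", 0, 0.5, saturated = TRUE)
  expect_warning(expect_message(e <- filter_track(allbad)), "all probes")
  expect_equal(nrow(e), 0)
})

test_that("state classification uses inclusive thresholds with high precedence", {
  th <- cna_thresholds()
  expect_identical(classify_state(0.25, th), "gain")
  expect_identical(classify_state(-0.30, th), "loss")
  expect_identical(classify_state(1.20, th), "high_gain")
  expect_identical(classify_state(-1.15, th), "high_loss")
  expect_identical(classify_state(0.0, th), "balanced")
  expect_identical(classify_state(c(0.201, -0.234, 1.14, -1.1), th),
                   c("gain", "loss", "high_gain", "high_loss"))
  expect_identical(classify_state(c(0.2009, -0.2339), th),
                   c("balanced", "balanced"))
  expect_error(cna_thresholds(gain = -0.1))
})

test_that("noise-free piecewise tracks are recovered exactly", {
  tr <- rle_track(c(0, 0.5, 0), c(20, 10, 20))
  seg <- segment_track(tr)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$n_probes, c(20, 10, 20))
  expect_equal(seg$mean_log2, c(0, 0.5, 0))
  expect_identical(seg$state, c("balanced", "gain", "balanced"))
  # idempotence: means equal the input levels exactly
  tr2 <- rle_track(c(-1.5, 0, 0.3, 1.5), c(10, 30, 12, 5))
  seg2 <- segment_track(tr2)
  expect_equal(seg2$mean_log2, c(-1.5, 0, 0.3, 1.5))
  expect_identical(seg2$state, c("high_loss", "balanced", "gain", "high_gain"))
})

test_that("a two-probe excursion is never called (minimum window three)", {
  tr <- rle_track(c(0, 2.0, 0), c(20, 2, 20))
  seg <- segment_track(tr)
  expect_false(any(seg$state != "balanced"))
  expect_equal(sum(seg$n_probes), 42)
  # three probes are enough
  tr3 <- rle_track(c(0, 2.0, 0), c(20, 3, 20))
  seg3 <- segment_track(tr3)
  expect_true(any(seg3$state == "high_gain"))
  expect_equal(seg3$n_probes[seg3$state == "high_gain"], 3)
})

test_that("segmentation partitions every chromosome's probes", {
  set.seed(92)
  for (i in 1:5) {
    tr <- simulate_cgh(data.frame(id = sprintf("p%03d", 1:150),
                                  chrom = rep(c("A1", "A2"), c(80, 70)),
                                  pos = c((1:80) * 2e4, (1:70) * 2e4)),
                       cna = data.frame(chrom = "A1", start = 4e5, end = 8e5,
                                        log2 = 0.5),
                       noise_sd = 0.15, seed = 92 + i)
    seg <- segment_track(tr)
    for (ch in c("A1", "A2"))
      expect_equal(sum(seg$n_probes[seg$chrom == ch]), sum(tr$chrom == ch))
    # segments are ordered and non-overlapping
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      expect_true(all(diff(s$start) > 0))
      expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("breakpoints are recovered under noise", {
  hits <- 0; total <- 0
  for (r in 1:50) {
    tr <- simulate_cgh(data.frame(id = sprintf("p%03d", 1:150), chrom = "A1",
                                  pos = (0:149) * 2e4),
                       cna = data.frame(chrom = "A1",
                                        start = c(6e5, 1.8e6),
                                        end = c(1.2e6, 2.4e6),
                                        log2 = c(0.5, -0.5)),
                       noise_sd = 0.15, seed = 900 + r)
    seg <- segment_track(tr)
    bnd <- seg$start[-1]  # detected changepoint positions
    for (truth in c(6e5, 1.2e6, 1.8e6, 2.4e6)) {
      total <- total + 1
      if (any(abs(bnd - truth) <= 2 * 2e4)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("raising the gain threshold never adds gain calls", {
  set.seed(93)
  tr <- simulate_cgh(data.frame(id = sprintf("p%03d", 1:200), chrom = "A1",
                                pos = (0:199) * 2e4),
                     cna = data.frame(chrom = "A1",
                                      start = c(4e5, 2e6), end = c(1e6, 2.6e6),
                                      log2 = c(0.25, 0.6)),
                     noise_sd = 0.1, seed = 93)
  counts <- sapply(c(0.15, 0.201, 0.3, 0.5, 0.7), function(gth) {
    seg <- segment_track(tr, cna_thresholds(gain = gth))
    sum(seg$state %in% c("gain", "high_gain"))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("gene overlap uses half-open arithmetic", {
  seg <- segment_track(rle_track(c(0, -1.5, 0), c(10, 5, 10), spacing = 1e4))
  loss <- seg[seg$state == "high_loss", ]
  genes <- data.frame(
    gene = c("PTEN", "ABUT", "INSIDE"),
    chrom = "chr1",
    start = c(loss$start - 5000, loss$end + 1, loss$start + 1000),
    end = c(loss$start + 5000, loss$end + 20000, loss$start + 2000))
  ann <- annotate_segments(seg, genes)
  got <- strsplit(ann$genes[ann$state == "high_loss"], ",")[[1]]
  expect_true(all(c("PTEN", "INSIDE") %in% got))
  expect_false("ABUT" %in% got)  # shared boundary only, zero overlap
})

test_that("ratio tracks and segments round-trip through TSV", {
  tr <- rle_track(c(0, 0.5), c(5, 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_track(tr, f)
  tr2 <- read_ratio_track(f)
  expect_equal(tr2$pos, tr$pos)
  expect_equal(tr2$log2, tr$log2)
  seg <- segment_track(tr)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_segments(seg, fb)
  bed <- read.delim(fb, header = FALSE)
  expect_equal(nrow(bed), nrow(seg))
  expect_equal(bed$V2, seg$start)
})
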