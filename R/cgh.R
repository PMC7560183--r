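# Copy-number analysis of aCGH ratio tracks: log2 ratio computation, probe
# QC filtering, least-squares changepoint segmentation, threshold-based
# state calling with a minimum probe window, and gene-overlap annotation.

#' Construct a ratio track
#'
#' An ordered per-probe table of log2 test:reference values with QC flags.
#' Positions are internal 0-based probe start offsets.
#'
#' @param probe probe ids.
#' @param chrom chromosome labels.
#' @param pos probe positions.
#' @param log2 log2 ratios.
#' @param non_uniform,saturated logical QC flags.
#' @param ... further per-probe columns carried through.
#' @return a `ratio_track` data frame, sorted by (chrom, pos).
#' @export
ratio_track <- function(probe, chrom, pos, log2, non_uniform = FALSE,
                        saturated = FALSE, ...) {
  df <- data.frame(probe = as.character(probe), chrom = as.character(chrom),
                   pos = as.numeric(pos), log2 = as.numeric(log2),
                   non_uniform = non_uniform, saturated = saturated, ...,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ratio_track", "data.frame")
  df
}

.SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "fcaX", "fcaY")

#' Compute log2 ratios from two-channel intensities
#'
#' Probes with a non-positive intensity in either channel are flagged
#' (`saturated`) and excluded, not raised as errors. Normalization mode
#' `"median"` centers the track on the autosomal median; `"none"` passes
#' raw log2 ratios.
#'
#' @param intensities data frame with columns `probe`, `chrom`, `pos`,
#'   `test`, `reference`.
#' @param normalization `"median"` or `"none"`.
#' @param sex_chroms chromosome labels excluded from the normalization
#'   median.
#' @return a `ratio_track`.
#' @export
compute_log2_ratios <- function(intensities,
                                normalization = c("median", "none"),
                                sex_chroms = .SEX_CHROMS) {
  normalization <- match.arg(normalization)
  need <- c("probe", "chrom", "pos", "test", "reference")
  miss <- setdiff(need, names(intensities))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !(intensities$test > 0 & intensities$reference > 0)
  if (any(bad))
    message(sum(bad), " probe(s) with non-positive intensity excluded")
  d <- intensities[!bad, , drop = FALSE]
  lr <- log2(d$test / d$reference)
  if (normalization == "median") {
    auto <- !(d$chrom %in% sex_chroms)
    if (!any(auto)) stop("no autosomal probes available for median centering")
    lr <- lr - stats::median(lr[auto])
  }
  ratio_track(d$probe, d$chrom, d$pos, lr)
}

#' Remove QC-flagged probes from a ratio track
#'
#' Drops probes flagged as non-uniform or saturated and reports the removal
#' count. Returns an empty track, with a warning, when every probe is
#' flagged.
#'
#' @param track a `ratio_track`.
#' @return the filtered `ratio_track`.
#' @export
filter_track <- function(track) {
  drop <- track$non_uniform | track$saturated
  if (any(drop)) message(sum(drop), " flagged probe(s) removed")
  out <- track[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all probes flagged; empty track")
  rownames(out) <- NULL
  class(out) <- c("ratio_track", "data.frame")
  out
}

#' Copy-number calling thresholds
#'
#' Segment-mean log2 thresholds for gain/loss and high-amplitude calls, and
#' the minimum number of consecutive probes a called segment must span.
#' Comparisons are inclusive.
#'
#' @param gain,loss log2 thresholds for copy number gain (>= gain) and loss
#'   (<= loss).
#' @param high_gain,high_loss thresholds for high-amplitude events.
#' @param min_probes minimum consecutive-probe window for a called segment.
#' @return an object of class `cna_thresholds`.
#' @export
cna_thresholds <- function(gain = 0.201, loss = -0.234,
                           high_gain = 1.14, high_loss = -1.1,
                           min_probes = 3L) {
  stopifnot(loss < 0, gain > 0, high_loss <= loss, high_gain >= gain,
            min_probes >= 1)
  structure(list(gain = gain, loss = loss, high_gain = high_gain,
                 high_loss = high_loss, min_probes = as.integer(min_probes)),
            class = "cna_thresholds")
}

.CNA_STATES <- c("high_loss", "loss", "balanced", "gain", "high_gain")

#' Classify a segment mean into a copy-number state
#'
#' High-amplitude thresholds take precedence; all comparisons are inclusive.
#'
#' @param mean_log2 segment mean log2 ratio(s); vectorized.
#' @param thresholds a `cna_thresholds`.
#' @return character vector of states among `high_loss`, `loss`,
#'   `balanced`, `gain`, `high_gain`.
#' @export
classify_state <- function(mean_log2, thresholds = cna_thresholds()) {
  stopifnot(all(is.finite(mean_log2)))
  out <- rep("balanced", length(mean_log2))
  out[mean_log2 >= thresholds$gain] <- "gain"
  out[mean_log2 <= thresholds$loss] <- "loss"
  out[mean_log2 >= thresholds$high_gain] <- "high_gain"
  out[mean_log2 <= thresholds$high_loss] <- "high_loss"
  out
}

# Least-squares binary segmentation of one numeric vector. Returns sorted
# breakpoints j (segment boundary after index j). A split is accepted when
# it reduces the residual sum of squares by more than `penalty`.
.binseg <- function(x, penalty) {
  n <- length(x)
  find <- function(l, r) {
    len <- r - l + 1
    if (len < 2) return(integer(0))
    v <- x[l:r]
    cs <- cumsum(v)
    tot <- cs[len]
    j <- seq_len(len - 1)
    gain <- cs[j]^2 / j + (tot - cs[j])^2 / (len - j) - tot^2 / len
    b <- which.max(gain)
    if (gain[b] <= penalty + 1e-12) return(integer(0))
    cut <- l + b - 1
    c(find(l, cut), cut, find(cut + 1, r))
  }
  find(1, n)
}

# Robust per-probe noise scale from successive differences.
.noise_sd <- function(x) {
  if (length(x) < 3) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

#' Segment a ratio track and call copy-number states
#'
#' Chromosomes are segmented independently by least-squares changepoint
#' detection (binary segmentation; a split is accepted when it reduces the
#' residual sum of squares by more than `penalty_mult * sigma^2 * log(n)`,
#' with sigma estimated robustly from successive probe differences).
#' Segments shorter than the minimum probe window are merged into the
#' flanking segment with the closer mean (ties to the left neighbor), so a
#' sub-minimum excursion can never form a called segment. Segment means are
#' then classified against the thresholds.
#'
#' @param track a filtered, sorted `ratio_track`.
#' @param thresholds a `cna_thresholds`.
#' @param penalty_mult penalty multiplier of the split-acceptance rule.
#' @return a `cna_segments` data frame: `chrom`, `start`, `end` (positions
#'   of the first and last probe), `n_probes`, `mean_log2`, `state`.
#' @export
segment_track <- function(track, thresholds = cna_thresholds(),
                          penalty_mult = 3) {
  res <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    x <- d$log2
    n <- length(x)
    if (n == 0) next
    sigma <- .noise_sd(x)
    pen <- penalty_mult * sigma^2 * log(max(n, 2))
    bps <- .binseg(x, pen)
    bounds <- c(0, bps, n)
    seg_n <- diff(bounds)
    means <- vapply(seq_along(seg_n), function(i)
      mean(x[(bounds[i] + 1):bounds[i + 1]]), 0.0)
    # merge sub-minimum segments into the neighbor with the closer mean
    while (length(seg_n) > 1 && any(seg_n < thresholds$min_probes)) {
      i <- which(seg_n < thresholds$min_probes)[which.min(seg_n[seg_n < thresholds$min_probes])]
      left_d <- if (i > 1) abs(means[i] - means[i - 1]) else Inf
      right_d <- if (i < length(seg_n)) abs(means[i] - means[i + 1]) else Inf
      j <- if (left_d <= right_d) i - 1 else i + 1
      a <- min(i, j); b <- max(i, j)
      means[a] <- (means[a] * seg_n[a] + means[b] * seg_n[b]) / (seg_n[a] + seg_n[b])
      seg_n[a] <- seg_n[a] + seg_n[b]
      means <- means[-b]; seg_n <- seg_n[-b]
    }
    ends <- cumsum(seg_n)
    starts <- c(1, utils::head(ends, -1) + 1)
    st <- classify_state(means, thresholds)
    # a lone sub-minimum segment cannot be called
    st[seg_n < thresholds$min_probes] <- "balanced"
    res[[ch]] <- data.frame(chrom = ch,
                            start = d$pos[starts], end = d$pos[ends],
                            n_probes = as.integer(seg_n), mean_log2 = means,
                            state = st, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_probes = integer(0), mean_log2 = numeric(0),
               state = character(0))
  rownames(out) <- NULL
  class(out) <- c("cna_segments", "data.frame")
  out
}

#' Annotate segments with overlapping genes
#'
#' A gene is reported for a segment iff their intervals overlap by at least
#' one base under half-open arithmetic (an abutting gene sharing only a
#' boundary is not reported). Segment intervals cover probe start positions
#' as `[start, end + 1)`.
#'
#' @param segments a `cna_segments` data frame.
#' @param genes gene annotation data frame from [read_genes()] (`gene`,
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @return `segments` with a `genes` character column (comma-separated
#'   symbols) plus a long-format attribute-free data frame in the
#'   `overlaps` attribute.
#' @export
annotate_segments <- function(segments, genes) {
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end + 1))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end))
  ov <- GenomicRanges::findOverlaps(seg_gr, gene_gr, minoverlap = 1L)
  hits <- data.frame(segment = S4Vectors::queryHits(ov),
                     gene = genes$gene[S4Vectors::subjectHits(ov)],
                     stringsAsFactors = FALSE)
  segments$genes <- vapply(seq_len(nrow(segments)), function(i)
    paste(hits$gene[hits$segment == i], collapse = ","), "")
  attr(segments, "overlaps") <- hits
  segments
}

#' Read/write ratio tracks and segments as TSV
#'
#' Files use 1-based positions; the internal representation is 0-based.
#'
#' @param track a `ratio_track`.
#' @param path file path.
#' @return the object read, or `path` invisibly when writing.
#' @export
write_ratio_track <- function(track, path) {
  out <- track
  out$pos <- out$pos + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratio_track
#' @export
read_ratio_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe", "chrom", "pos", "log2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  ratio_track(df$probe, df$chrom, df$pos - 1, df$log2,
              non_uniform = if ("non_uniform" %in% names(df)) df$non_uniform else FALSE,
              saturated = if ("saturated" %in% names(df)) df$saturated else FALSE)
}

#' Write called segments as BED5+
#'
#' Columns: chrom, start (0-based), end, state, mean log2, probe count.
#'
#' @param segments a `cna_segments`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end + 1, name = segments$state,
                    score = segments$mean_log2, n_probes = segments$n_probes)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
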