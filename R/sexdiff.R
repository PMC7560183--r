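# Sex-mismatch (female vs male) hybridization analysis: chromosome-level
# mean log2 summaries with region exclusion, detection of the
# pseudoautosomal-region (PAR) boundary as the balanced-to-gained
# transition along X, and discordant autosomal region calling.

#' Mean log2 ratio along a chromosome
#'
#' Arithmetic mean over the chromosome's probes, optionally omitting probes
#' inside an exclusion interval (0-based half-open), e.g. the PAR when
#' summarizing the X-specific dosage difference.
#'
#' @param track a `ratio_track`.
#' @param chrom chromosome label.
#' @param exclude optional length-2 vector `c(start, end)`.
#' @return mean log2 ratio.
#' @export
chromosome_mean <- function(track, chrom, exclude = NULL) {
  d <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) stop("no probes on chromosome ", chrom)
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == 2, exclude[1] < exclude[2])
    d <- d[!(d$pos >= exclude[1] & d$pos < exclude[2]), , drop = FALSE]
    if (nrow(d) == 0) stop("no probes remain after exclusion on ", chrom)
  }
  mean(d$log2)
}

#' Detect the pseudoautosomal-region boundary on X
#'
#' In a female-vs-male hybridization the PAR at the X terminus appears
#' copy-number balanced while the X-specific remainder appears gained.
#' The boundary is reported as the open window between the last balanced
#' probe of the initial run and the first probe of the first sustained
#' gained run: at least `k` consecutive probes at or above the gain
#' threshold, from whose start the next `persist_window` probes (or the
#' track remainder, if shorter) remain predominantly gained (fraction at
#' least `persist`). Isolated stray probes -- or short noise runs -- inside
#' the balanced head therefore do not trigger a transition.
#'
#' @param track a `ratio_track` containing the X chromosome, sorted from
#'   the p-terminus.
#' @param chrom the X chromosome's label in the track.
#' @param thresholds a `cna_thresholds` (the gain threshold defines
#'   "unbalanced"; "balanced" means |log2| below it).
#' @param k sustained-run length.
#' @param persist minimum gained fraction over the look-ahead window for a
#'   run to count as the transition.
#' @param persist_window look-ahead window length, probes.
#' @param genes optional gene annotation (from [read_genes()]); the genes
#'   nearest to (or containing) each flanking probe are reported.
#' @return an object of class `par_boundary`: list with
#'   `last_balanced_pos`, `first_unbalanced_pos`, `window_bp`, and
#'   `proximal_gene`/`distal_gene` when an annotation is supplied. A
#'   track gained from the first probe yields a degenerate boundary with
#'   `last_balanced_pos = NA` at the track start.
#' @export
detect_par_boundary <- function(track, chrom = "X",
                                thresholds = cna_thresholds(), k = 3L,
                                persist = 0.8, persist_window = 20L,
                                genes = NULL) {
  d <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) stop("no probes on chromosome ", chrom)
  d <- d[order(d$pos), , drop = FALSE]
  gained <- d$log2 >= thresholds$gain
  n <- nrow(d)
  # maximal runs of gained probes with length >= k, in track order
  r <- rle(gained)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  starts <- lo[r$values & r$lengths >= k]
  # the transition run must remain predominantly gained over the look-ahead
  cg <- c(0, cumsum(gained))
  ahead <- pmin(starts + persist_window - 1L, n)
  frac <- (cg[ahead + 1] - cg[starts]) / (ahead - starts + 1)
  starts <- starts[frac >= persist]
  if (length(starts) == 0) stop("no transition detected on ", chrom)
  s <- starts[1]
  first_pos <- d$pos[s]
  balanced <- abs(d$log2) < thresholds$gain
  lb <- which(balanced[seq_len(s - 1)])
  if (s == 1 || length(lb) == 0) {
    res <- list(chrom = chrom, last_balanced_pos = NA_real_,
                first_unbalanced_pos = first_pos, window_bp = NA_real_,
                degenerate = TRUE)
  } else {
    last_pos <- d$pos[max(lb)]
    res <- list(chrom = chrom, last_balanced_pos = last_pos,
                first_unbalanced_pos = first_pos,
                window_bp = first_pos - last_pos, degenerate = FALSE)
  }
  if (!is.null(genes) && !res$degenerate) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    nearest <- function(pos) {
      if (nrow(g) == 0) return(NA_character_)
      inside <- g$start <= pos & g$end > pos
      if (any(inside)) return(g$gene[inside][1])
      g$gene[which.min(pmin(abs(g$start - pos), abs(g$end - 1 - pos)))]
    }
    res$proximal_gene <- nearest(res$last_balanced_pos)
    res$distal_gene <- nearest(res$first_unbalanced_pos)
  }
  structure(res, class = "par_boundary")
}

#' @export
print.par_boundary <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("PAR boundary (degenerate): gained from first probe at %s:%s\n",
                x$chrom, format(x$first_unbalanced_pos + 1, big.mark = ",")))
  } else {
    cat(sprintf("PAR boundary window %s:%s-%s (%s bp)\n", x$chrom,
                format(x$last_balanced_pos + 1, big.mark = ","),
                format(x$first_unbalanced_pos + 1, big.mark = ","),
                format(x$window_bp, big.mark = ",")))
    if (!is.null(x$proximal_gene))
      cat(sprintf("  flanking genes: %s | %s\n", x$proximal_gene, x$distal_gene))
  }
  invisible(x)
}

#' Find discordant autosomal regions in a sex-mismatch track
#'
#' Segments the autosomal portion of the track and reports every called
#' (non-balanced) segment with its probe count and span.
#'
#' @param track a `ratio_track`.
#' @param thresholds a `cna_thresholds`.
#' @param sex_chroms chromosome labels excluded as sex chromosomes.
#' @param penalty_mult passed to [segment_track()].
#' @return a `cna_segments` data frame of non-balanced autosomal segments
#'   with an added `span_bp` column.
#' @export
find_discordant_autosomal_regions <- function(track,
                                              thresholds = cna_thresholds(),
                                              sex_chroms = .SEX_CHROMS,
                                              penalty_mult = 3) {
  auto <- track[!(track$chrom %in% sex_chroms), , drop = FALSE]
  segs <- segment_track(auto, thresholds, penalty_mult)
  out <- segs[segs$state != "balanced", , drop = FALSE]
  out$span_bp <- out$end - out$start
  rownames(out) <- NULL
  out
}
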