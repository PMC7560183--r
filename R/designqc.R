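# Probe-distribution design QC: per-chromosome spacing summaries, outlier
# intervals, interval coverage fractions, and the probe-fate accounting
# report of the migration ledger.

#' Per-chromosome probe spacing summary
#'
#' Spacing is defined start-to-start between consecutive probes, the common
#' array convention (mean spacing is then approximately chromosome span /
#' (N - 1)). Probes per Mb is the rounded count per megabase of chromosome.
#'
#' @param starts sorted probe start positions on one chromosome.
#' @param chrom_size chromosome size in bp.
#' @param chrom chromosome label.
#' @return one-row data frame: `chrom`, `size`, `n_probes`, `mean_spacing`,
#'   `median_spacing`, `max_spacing`, `probes_per_mb`. Spacing fields are NA
#'   when fewer than 2 probes are present.
#' @export
spacing_summary <- function(starts, chrom_size, chrom = NA_character_) {
  starts <- sort(as.numeric(starts))
  n <- length(starts)
  if (n >= 2) {
    iv <- diff(starts)
    ms <- mean(iv); md <- stats::median(iv); mx <- max(iv)
  } else {
    warning("fewer than 2 probes on ", chrom, "; spacing undefined")
    ms <- md <- mx <- NA_real_
  }
  data.frame(chrom = chrom, size = as.numeric(chrom_size), n_probes = n,
             mean_spacing = ms, median_spacing = md, max_spacing = mx,
             probes_per_mb = round(n / (chrom_size / 1e6)),
             stringsAsFactors = FALSE)
}

#' Outlier probe intervals (boxplot rule)
#'
#' An interval is an outlier when it is strictly larger than
#' Q3 + 1.5 (Q3 - Q1).
#'
#' @param intervals numeric vector of inter-probe distances.
#' @param qtype quantile algorithm passed to [stats::quantile()].
#' @return the outlying interval values (empty, with a warning, for fewer
#'   than 4 intervals).
#' @export
outlier_intervals <- function(intervals, qtype = 7) {
  if (length(intervals) < 4) {
    warning("fewer than 4 intervals; outlier rule not applied")
    return(numeric(0))
  }
  q <- stats::quantile(intervals, c(0.25, 0.75), type = qtype, names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  intervals[intervals > thr]
}

#' Interval coverage fractions below size thresholds
#'
#' @param intervals inter-probe distances, bp.
#' @param thresholds size thresholds, bp.
#' @return list with `table` (threshold, fraction strictly below, count
#'   strictly below) and `n_above_max` (count strictly above the largest
#'   threshold).
#' @export
coverage_fractions <- function(intervals, thresholds = c(5e4, 1e5, 1e6)) {
  stopifnot(length(intervals) > 0)
  thresholds <- sort(thresholds)
  tab <- data.frame(threshold = thresholds,
                    n_below = vapply(thresholds, function(t) sum(intervals < t), 0L),
                    fraction_below = vapply(thresholds, function(t)
                      mean(intervals < t), 0.0))
  list(table = tab, n_above_max = sum(intervals > max(thresholds)))
}

#' Genome-wide probe spacing report
#'
#' Per-chromosome spacing summaries plus a totals row. The totals row
#' reports the sum of chromosome sizes and probe counts, and two flavours
#' of the genome-wide averages: the unweighted mean of per-chromosome values
#' (the convention of per-chromosome design summary tables) and pooled
#' values over all intervals.
#'
#' @param probes a `probe_set` (or data frame with `chrom` and `start`).
#' @param chrom_sizes named vector of chromosome sizes, bp.
#' @param thresholds coverage thresholds, bp.
#' @param gaps optional data frame of assembly gaps (`chrom`, `start`,
#'   `end`, 0-based half-open); outlier intervals overlapping a gap are
#'   flagged.
#' @return an object of class `spacing_report`: list with `per_chrom`,
#'   `totals`, `coverage`, `outliers`.
#' @export
genome_spacing_report <- function(probes, chrom_sizes,
                                  thresholds = c(5e4, 1e5, 1e6), gaps = NULL) {
  chroms <- names(chrom_sizes)
  per <- do.call(rbind, lapply(chroms, function(ch) {
    spacing_summary(probes$start[probes$chrom == ch], chrom_sizes[[ch]], ch)
  }))
  all_iv <- unlist(lapply(chroms, function(ch) {
    s <- sort(probes$start[probes$chrom == ch])
    if (length(s) >= 2) diff(s) else numeric(0)
  }))
  out <- do.call(rbind, lapply(chroms, function(ch) {
    s <- sort(probes$start[probes$chrom == ch])
    if (length(s) < 2) return(NULL)
    iv <- diff(s)
    o <- suppressWarnings(outlier_intervals(iv))
    if (length(o) == 0) return(NULL)
    idx <- which(iv %in% o)
    df <- data.frame(chrom = ch, start = s[idx], end = s[idx + 1],
                     size = iv[idx], stringsAsFactors = FALSE)
    df
  }))
  if (!is.null(out) && nrow(out) > 0) {
    out$in_gap <- FALSE
    if (!is.null(gaps)) {
      for (i in seq_len(nrow(out)))
        out$in_gap[i] <- any(gaps$chrom == out$chrom[i] &
                               gaps$start < out$end[i] & gaps$end > out$start[i])
    }
  }
  totals <- list(
    size = sum(per$size), n_probes = sum(per$n_probes),
    mean_spacing_per_chrom = round(mean(per$mean_spacing, na.rm = TRUE)),
    probes_per_mb_per_chrom = round(mean(per$probes_per_mb, na.rm = TRUE)),
    mean_spacing_pooled = if (length(all_iv)) round(mean(all_iv)) else NA_real_,
    probes_per_mb_pooled = round(sum(per$n_probes) / (sum(per$size) / 1e6)))
  structure(list(per_chrom = per, totals = totals,
                 coverage = coverage_fractions(all_iv, thresholds),
                 outliers = out),
            class = "spacing_report")
}

#' Totals row of a per-chromosome design summary table
#'
#' Reproduces the totals-row convention of per-chromosome probe-distribution
#' tables: summed sizes and counts, and unweighted means of the
#' per-chromosome mean spacings and probes/Mb.
#'
#' @param table data frame with columns `size`, `n_probes`, `mean_spacing`,
#'   `probes_per_mb` (one row per chromosome).
#' @return list with `size`, `n_probes`, `mean_spacing`, `probes_per_mb`.
#' @export
summary_table_totals <- function(table) {
  list(size = sum(table$size),
       n_probes = sum(table$n_probes),
       mean_spacing = round(mean(table$mean_spacing)),
       probes_per_mb = round(mean(table$probes_per_mb)))
}

#' Published feline oaCGH design summary
#'
#' The per-chromosome probe-distribution summary of the 110,456-probe feline
#' oaCGH array design (chromosome size, validated probe count, mean/median/
#' maximum start-to-start spacing, probes per Mb), shipped as a plain TSV.
#'
#' @return data frame with one row per chromosome.
#' @export
design_summary_table <- function() {
  path <- system.file("extdata", "feline_oacgh_design_summary.tsv",
                      package = "cghlift")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Probe-fate accounting report
#'
#' Derives and validates the stage arithmetic of a migration ledger: total
#' input probes split into alignment failures and successful alignments;
#' successes split into exact matches, directly usable orthologs, and
#' boundary-adjustment attempts (of which some fail on nucleotide
#' composition); candidates reduced to the final design by removal of
#' probes with inconclusive map assignments.
#'
#' @param ledger a `migration_ledger`, or a list with fields `total`,
#'   `no_alignment`, `exact_match`, `direct_ortholog`, `adjusted`,
#'   `failed_adjust`, `ambiguous_map`.
#' @return an object of class `accounting_report`: list with the input
#'   counts plus `aligned`, `failure_pct` (rounded percent), `candidates`,
#'   `adjust_attempted`, `unadjustable` and `final`.
#' @export
accounting_report <- function(ledger) {
  l <- unclass(ledger)
  need <- c("total", "no_alignment", "exact_match", "direct_ortholog",
            "adjusted", "failed_adjust", "ambiguous_map")
  miss <- setdiff(need, names(l))
  if (length(miss) > 0) stop("ledger missing field(s): ", paste(miss, collapse = ", "))
  candidates <- l$exact_match + l$direct_ortholog + l$adjusted
  if (l$no_alignment + candidates + l$failed_adjust != l$total)
    stop("inconsistent ledger: no_alignment + candidates + failed_adjust != total (",
         l$no_alignment, " + ", candidates, " + ", l$failed_adjust,
         " != ", l$total, ")")
  if (l$ambiguous_map > candidates)
    stop("inconsistent ledger: ambiguous_map exceeds candidates")
  rep <- list(total = l$total,
              no_alignment = l$no_alignment,
              aligned = l$total - l$no_alignment,
              failure_pct = round(100 * l$no_alignment / l$total),
              exact_match = l$exact_match,
              direct_ortholog = l$direct_ortholog,
              adjusted = l$adjusted,
              adjust_attempted = l$adjusted + l$failed_adjust,
              unadjustable = l$failed_adjust,
              candidates = candidates,
              ambiguous_map = l$ambiguous_map,
              final = candidates - l$ambiguous_map)
  structure(rep, class = "accounting_report")
}

#' @export
print.accounting_report <- function(x, ...) {
  cat("Probe accounting\n")
  cat(sprintf("  input probes        %9s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  no robust alignment %9s (%d%%)\n",
              format(x$no_alignment, big.mark = ","), x$failure_pct))
  cat(sprintf("  aligned             %9s\n", format(x$aligned, big.mark = ",")))
  cat(sprintf("    exact match       %9s\n", format(x$exact_match, big.mark = ",")))
  cat(sprintf("    direct ortholog   %9s\n", format(x$direct_ortholog, big.mark = ",")))
  cat(sprintf("    adjustment tried  %9s\n", format(x$adjust_attempted, big.mark = ",")))
  cat(sprintf("      adjusted        %9s\n", format(x$adjusted, big.mark = ",")))
  cat(sprintf("      unadjustable    %9s\n", format(x$unadjustable, big.mark = ",")))
  cat(sprintf("  candidate probes    %9s\n", format(x$candidates, big.mark = ",")))
  cat(sprintf("  ambiguous map       %9s\n", format(x$ambiguous_map, big.mark = ",")))
  cat(sprintf("  final design        %9s\n", format(x$final, big.mark = ",")))
  invisible(x)
}
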