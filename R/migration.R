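# Cross-species probe migration: extend each template probe with flanking
# sequence, locate the unambiguous ortholog in the target assembly, extract
# the orthologous core, adjust its boundaries to the template's Tm/GC
# profile, and verify that the candidate maps to a unique target locus.
# Every probe's fate is accounted for in a migration ledger.

.MIGRATION_STATUSES <- c("no_alignment", "exact_match", "direct_ortholog",
                         "adjusted", "failed_adjust", "ambiguous_map")

#' Extend a probe with flanking template sequence
#'
#' Returns the template-genome substring spanning `flank` bases either side
#' of the probe (clipped at chromosome bounds) together with the offset of
#' the probe core within the extension. A 60-mer with the default 100-nt
#' flanks yields a 260-nt extended query.
#'
#' @param probe one-row slice of a `probe_set` (or list with `chrom`,
#'   `start`, `end`).
#' @param genome the template `genome_assembly`.
#' @param flank bases added to each end.
#' @return list with `sequence`, `chrom`, `start`, `end` (0-based half-open
#'   extension interval), `core_offset` (0-based offset of the core within
#'   the extension) and `core_length`.
#' @export
extend_probe <- function(probe, genome, flank = 100L) {
  len <- seq_lengths(genome)[[probe$chrom]]
  s <- max(0L, probe$start - as.integer(flank))
  e <- min(len, probe$end + as.integer(flank))
  list(sequence = get_subsequence(genome, probe$chrom, s, e),
       chrom = probe$chrom, start = s, end = e,
       core_offset = probe$start - s,
       core_length = probe$end - probe$start)
}

#' Locate the unambiguous ortholog of an extended probe
#'
#' Runs the seeded local aligner against every sequence of the target
#' assembly. The best hit is reported when it is robust (identity at least
#' `min_identity` over at least `min_query_frac` of the query) and
#' unambiguous (best score at least `ambiguity_margin` times the best score
#' at any distinct locus).
#'
#' @param extended_seq extended query (see [extend_probe()]).
#' @param target_genome target `genome_assembly`.
#' @param min_identity minimum alignment identity.
#' @param min_query_frac minimum aligned fraction of the query.
#' @param ambiguity_margin multiplicative score margin over the second-best
#'   distinct locus.
#' @param params an `align_params`.
#' @return list with `status` (`"hit"`, `"no_alignment"` or
#'   `"ambiguous_map"`) and, unless no alignment was found, `hit` (the best
#'   hit, as in [seeded_align()]).
#' @export
find_ortholog <- function(extended_seq, target_genome, min_identity = 0.75,
                          min_query_frac = 0.5, ambiguity_margin = 1.1,
                          params = align_params()) {
  hits <- seeded_align(extended_seq, target_genome, params)
  qlen <- nchar(extended_seq)
  robust <- Filter(function(h) {
    h$identity >= min_identity && (h$qend - h$qstart + 1) >= min_query_frac * qlen
  }, hits)
  if (length(robust) == 0) return(list(status = "no_alignment"))
  loci <- .distinct_hits(robust)
  best <- loci[[1]]
  if (length(loci) > 1 && best$score < ambiguity_margin * loci[[2]]$score)
    return(list(status = "ambiguous_map", hit = best, second = loci[[2]]))
  list(status = "hit", hit = best)
}

#' Extract the target-genome core of an aligned extension
#'
#' Walks the aligned-column map of a hit and returns the target positions
#' aligned to the template core's columns, dropping gap columns. Fails when
#' fewer than `min_core_frac` of the core columns are aligned.
#'
#' @param hit a hit from [find_ortholog()]/[seeded_align()].
#' @param core_offset 0-based offset of the core within the query.
#' @param core_length core length, nt.
#' @param min_core_frac minimum aligned fraction of core columns.
#' @return list with `status` (`"ok"` or `"unaligned"`) and, on success,
#'   `chrom`, `start`, `end` (0-based half-open target interval) and
#'   `aligned_frac`.
#' @export
extract_core <- function(hit, core_offset, core_length, min_core_frac = 0.8) {
  lo <- core_offset + 1L
  hi <- core_offset + core_length
  sel <- hit$qmap >= lo & hit$qmap <= hi
  frac <- sum(sel) / core_length
  if (frac < min_core_frac) return(list(status = "unaligned", aligned_frac = frac))
  spos <- hit$smap[sel]
  list(status = "ok", chrom = hit$chrom,
       start = min(spos) - 1L, end = max(spos),
       aligned_frac = frac)
}

#' Verify that a candidate probe maps to a unique target locus
#'
#' A candidate is unique iff exactly one locus of the target assembly aligns
#' to it with at least `near_match_identity` matches over the candidate's
#' full length.
#'
#' @param sequence candidate probe sequence.
#' @param target_genome target `genome_assembly`.
#' @param near_match_identity identity threshold counting a locus as a
#'   near-match (matches / candidate length).
#' @param params an `align_params`.
#' @return list with `status` (`"unique"`, `"ambiguous_map"` or
#'   `"no_alignment"`), `n_loci`, and the best `hit` when one exists.
#' @export
verify_unique <- function(sequence, target_genome, near_match_identity = 0.9,
                          params = align_params()) {
  hits <- seeded_align(sequence, target_genome, params)
  qlen <- nchar(sequence)
  qual <- Filter(function(h) h$matches / qlen >= near_match_identity, hits)
  loci <- .distinct_hits(qual)
  n <- length(loci)
  if (n == 0) return(list(status = "no_alignment", n_loci = 0L))
  list(status = if (n == 1) "unique" else "ambiguous_map",
       n_loci = n, hit = loci[[1]])
}

#' Migrate a template probe set to a target genome
#'
#' The full design cascade, applied independently to each template probe:
#' extension with flanking template sequence, ortholog search across all
#' target sequences, core extraction, thermodynamic classification
#' (exact match, direct use, or boundary adjustment against the template
#' probe's Tm/GC), and a final uniqueness pass that demotes candidates
#' without a unique target locus to `ambiguous_map`. Per-probe failures are
#' recorded as statuses, never raised as errors.
#'
#' @param probes template `probe_set` (with sequences, tm, gc).
#' @param template_genome,target_genome `genome_assembly` objects.
#' @param thermo a `thermo_params`.
#' @param align an `align_params`.
#' @param flank extension flank, nt.
#' @param min_identity,min_query_frac,ambiguity_margin see [find_ortholog()].
#' @param min_core_frac see [extract_core()].
#' @param near_match_identity see [verify_unique()].
#' @param adjust_flank extra target context either side of the core made
#'   available to boundary adjustment.
#' @return an object of class `migration_result`: list with `records` (one
#'   data-frame row per template probe: `id`, `status`, `stage_class`,
#'   `chrom`, `start`, `end` (0-based half-open target interval), `sequence`,
#'   `tm`, `gc`, `identity`, `notes`) and `ledger` (a `migration_ledger`).
#' @export
migrate_probes <- function(probes, template_genome, target_genome,
                           thermo = thermo_params(), align = align_params(),
                           flank = 100L, min_identity = 0.75,
                           min_query_frac = 0.5, ambiguity_margin = 1.1,
                           min_core_frac = 0.8, near_match_identity = 0.9,
                           adjust_flank = 50L) {
  n <- nrow(probes)
  rec <- data.frame(id = probes$id,
                    status = NA_character_, stage_class = NA_character_,
                    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
                    sequence = NA_character_, tm = NA_real_, gc = NA_real_,
                    identity = NA_real_, notes = "",
                    stringsAsFactors = FALSE)
  tlens <- seq_lengths(target_genome)
  for (i in seq_len(n)) {
    p <- probes[i, ]
    ext <- extend_probe(p, template_genome, flank)
    fo <- find_ortholog(ext$sequence, target_genome, min_identity,
                        min_query_frac, ambiguity_margin, align)
    if (fo$status == "no_alignment") {
      rec$status[i] <- rec$stage_class[i] <- "no_alignment"
      next
    }
    ambiguous_locus <- fo$status == "ambiguous_map"
    hit <- fo$hit
    rec$identity[i] <- hit$identity
    core <- extract_core(hit, ext$core_offset, ext$core_length, min_core_frac)
    if (core$status != "ok") {
      rec$status[i] <- rec$stage_class[i] <- "no_alignment"
      rec$notes[i] <- sprintf("core aligned fraction %.2f below threshold",
                              core$aligned_frac)
      next
    }
    core_seq <- get_subsequence(target_genome, core$chrom, core$start, core$end)
    cand <- NULL
    if (identical(core_seq, p$sequence)) {
      rec$stage_class[i] <- "exact_match"
      cand <- list(chrom = core$chrom, start = core$start, end = core$end,
                   sequence = core_seq,
                   tm = melting_temperature(core_seq, thermo),
                   gc = gc_content(core_seq))
    } else {
      clen <- nchar(core_seq)
      usable <- !grepl("[^ACGT]", core_seq) &&
        clen >= thermo$min_len && clen <= thermo$max_len
      ctm <- if (usable) melting_temperature(core_seq, thermo) else NA_real_
      cgc <- if (usable) gc_content(core_seq) else NA_real_
      if (usable && abs(ctm - p$tm) <= thermo$tm_tolerance &&
          abs(cgc - p$gc) <= thermo$gc_tolerance) {
        rec$stage_class[i] <- "direct_ortholog"
        cand <- list(chrom = core$chrom, start = core$start, end = core$end,
                     sequence = core_seq, tm = ctm, gc = cgc)
      } else {
        cs <- max(0L, core$start - as.integer(adjust_flank))
        ce <- min(tlens[[core$chrom]], core$end + as.integer(adjust_flank))
        context <- get_subsequence(target_genome, core$chrom, cs, ce)
        adj <- adjust_probe(context, core$start - cs + 1L, core$end - cs,
                            p$tm, p$gc, thermo)
        if (adj$status == "failed_adjust") {
          rec$status[i] <- rec$stage_class[i] <- "failed_adjust"
          next
        }
        rec$stage_class[i] <- "adjusted"
        cand <- list(chrom = core$chrom,
                     start = cs + adj$start - 1L, end = cs + adj$end,
                     sequence = adj$sequence, tm = adj$tm, gc = adj$gc)
      }
    }
    # uniqueness pass
    uq <- verify_unique(cand$sequence, target_genome, near_match_identity, align)
    if (ambiguous_locus || uq$status != "unique") {
      rec$status[i] <- "ambiguous_map"
      rec$notes[i] <- if (ambiguous_locus) "ambiguous ortholog locus"
      else sprintf("%d near-match loci", uq$n_loci)
    } else {
      rec$status[i] <- rec$stage_class[i]
    }
    rec$chrom[i] <- cand$chrom
    rec$start[i] <- cand$start
    rec$end[i] <- cand$end
    rec$sequence[i] <- cand$sequence
    rec$tm[i] <- cand$tm
    rec$gc[i] <- cand$gc
  }
  # scrub target fields for non-success final statuses (record invariant)
  fail <- !(rec$status %in% c("exact_match", "direct_ortholog", "adjusted"))
  rec$chrom[fail] <- NA_character_
  rec$start[fail] <- NA_integer_
  rec$end[fail] <- NA_integer_
  rec$sequence[fail] <- NA_character_
  rec$tm[fail] <- NA_real_
  rec$gc[fail] <- NA_real_
  structure(list(records = rec, ledger = migration_ledger(rec)),
            class = "migration_result")
}

#' Build a migration ledger from migration records
#'
#' Stage-class counts follow the design cascade (before the uniqueness
#' pass); `candidates` is the sum of the three success classes,
#' `ambiguous_map` the number of candidates demoted for lacking a unique
#' target locus, and `final` the probes emitted on the target design.
#'
#' @param records the `records` data frame of a `migration_result`.
#' @return an object of class `migration_ledger`.
#' @export
migration_ledger <- function(records) {
  stage <- table(factor(records$stage_class,
                        levels = c("no_alignment", "exact_match",
                                   "direct_ortholog", "adjusted", "failed_adjust")))
  led <- list(total = nrow(records),
              no_alignment = unname(stage[["no_alignment"]]),
              exact_match = unname(stage[["exact_match"]]),
              direct_ortholog = unname(stage[["direct_ortholog"]]),
              adjusted = unname(stage[["adjusted"]]),
              failed_adjust = unname(stage[["failed_adjust"]]),
              ambiguous_map = sum(records$status == "ambiguous_map"))
  led$candidates <- led$exact_match + led$direct_ortholog + led$adjusted
  led$final <- led$candidates - led$ambiguous_map
  structure(led, class = "migration_ledger")
}

#' @export
print.migration_ledger <- function(x, ...) {
  cat("Migration ledger\n")
  cat(sprintf("  input probes       %8d\n", x$total))
  cat(sprintf("  no alignment       %8d\n", x$no_alignment))
  cat(sprintf("  exact match        %8d\n", x$exact_match))
  cat(sprintf("  direct ortholog    %8d\n", x$direct_ortholog))
  cat(sprintf("  adjusted           %8d\n", x$adjusted))
  cat(sprintf("  failed adjustment  %8d\n", x$failed_adjust))
  cat(sprintf("  candidates         %8d\n", x$candidates))
  cat(sprintf("  ambiguous map      %8d\n", x$ambiguous_map))
  cat(sprintf("  final design       %8d\n", x$final))
  invisible(x)
}

#' Write migration records and ledger as TSV
#'
#' Records are written with 1-based inclusive target coordinates.
#'
#' @param result a `migration_result`.
#' @param records_path,ledger_path output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_migration <- function(result, records_path, ledger_path = NULL) {
  rec <- result$records
  out <- data.frame(id = rec$id, status = rec$status,
                    chrom = rec$chrom,
                    start = rec$start + 1L, end = rec$end,
                    sequence = rec$sequence, tm = rec$tm, gc = rec$gc,
                    identity = rec$identity, notes = rec$notes)
  utils::write.table(out, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ledger_path)) {
    led <- result$ledger
    utils::write.table(
      data.frame(stage = names(unclass(led)), count = unlist(led)),
      ledger_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
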