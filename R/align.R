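# Local alignment engine: k-mer seeded chain-and-extend with affine-gap
# Smith-Waterman extension over candidate windows. Self-contained so the
# migration pipeline needs no external aligner; the scoring interface is
# pluggable through `align_params`.

#' Alignment parameters
#'
#' Scoring and seeding settings for the built-in seeded local aligner. A gap
#' of length L costs `gap_open + L * gap_ext`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open,gap_ext affine gap penalties (>= 0).
#' @param k seed k-mer length.
#' @param band diagonal band width used when clustering seeds.
#' @param max_hits maximum number of hits returned per target sequence.
#' @return an object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 2, gap_ext = 1,
                         k = 11L, band = 48L, max_hits = 20L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext >= 0,
            k >= 4, k <= 31, band >= 0, max_hits >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, k = as.integer(k), band = as.integer(band),
                 max_hits = as.integer(max_hits)),
            class = "align_params")
}

#' Full Smith-Waterman local alignment
#'
#' Exhaustive affine-gap dynamic programming over the full query x subject
#' matrix. Intended for short sequences; the seeded search scales to
#' genome-sized subjects.
#'
#' @param query,subject nucleotide strings.
#' @param params an `align_params`.
#' @return list with `score`, 1-based `qstart`/`qend`/`sstart`/`send`,
#'   `matches`, `ncols` (alignment columns incl. gaps), `identity`
#'   (matches/ncols) and the aligned-column maps `qmap`/`smap`.
#' @export
sw_align <- function(query, subject, params = align_params()) {
  r <- cpp_sw_align(toupper(query), toupper(subject), params$match,
                    params$mismatch, params$gap_open, params$gap_ext)
  r$identity <- if (r$ncols > 0) r$matches / r$ncols else 0
  r
}

#' Seeded local alignment against an assembly
#'
#' Finds exact k-mer seeds, clusters them by diagonal, and extends each
#' candidate window by full affine-gap local alignment. Hits are returned
#' across all sequences of the assembly, best score first.
#'
#' @param query nucleotide string.
#' @param genome a `genome_assembly` (or named character vector).
#' @param params an `align_params`.
#' @return list of hits; each hit as in [sw_align()] plus `chrom`.
#' @export
seeded_align <- function(query, genome, params = align_params()) {
  if (length(genome) == 0) stop("empty target genome")
  query <- toupper(query)
  hits <- list()
  for (chrom in names(genome)) {
    hs <- cpp_seeded_hits(query, genome[[chrom]], params$k, params$match,
                          params$mismatch, params$gap_open, params$gap_ext,
                          params$band, params$max_hits)
    for (h in hs) {
      h$chrom <- chrom
      h$identity <- if (h$ncols > 0) h$matches / h$ncols else 0
      hits[[length(hits) + 1]] <- h
    }
  }
  if (length(hits) == 0) return(hits)
  hits[order(vapply(hits, `[[`, 0.0, "score"), decreasing = TRUE)]
}

# TRUE when two hits occupy distinct loci (different sequence, or
# non-overlapping subject intervals on the same sequence).
.distinct_locus <- function(a, b) {
  if (!identical(a$chrom, b$chrom)) return(TRUE)
  a$send < b$sstart || b$send < a$sstart
}

# Collapse hits into distinct loci, keeping the best-scoring hit per locus.
.distinct_hits <- function(hits) {
  kept <- list()
  for (h in hits) {
    dup <- FALSE
    for (kk in kept) if (!.distinct_locus(h, kk)) { dup <- TRUE; break }
    if (!dup) kept[[length(kept) + 1]] <- h
  }
  kept
}
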