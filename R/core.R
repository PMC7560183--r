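#' @useDynLib cghlift, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
#' @import utils
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# All file I/O and printed reports use 1-based inclusive coordinates,
# which is what genome browsers and the array literature print.

#' Construct a genome assembly
#'
#' A genome assembly is a named set of nucleotide sequences (chromosomes or
#' scaffolds) restricted to the alphabet A/C/G/T/N. Sequences are uppercased
#' and any other character is mapped to N.
#'
#' @param sequences named character vector of nucleotide strings.
#' @param name optional text label for the assembly.
#' @return an object of class `genome_assembly`.
#' @export
genome_assembly <- function(sequences, name = "genome") {
  if (length(sequences) == 0) stop("assembly must contain at least one sequence")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- toupper(sequences)
  sequences <- gsub("[^ACGTN]", "N", sequences)
  if (any(nchar(sequences) < 1)) stop("zero-length sequence in assembly")
  structure(sequences, name = name, class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly '%s': %d sequence(s), %s bp total>\n",
              attr(x, "name"), length(x),
              format(sum(nchar(unclass(x))), big.mark = ",")))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param genome a `genome_assembly`.
#' @return named integer vector of sequence lengths.
#' @export
seq_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Read a FASTA file into a genome assembly
#'
#' Sequences are uppercased and non-ACGTN characters are mapped to N.
#'
#' @param path path to a FASTA file.
#' @param name assembly label; defaults to the file name.
#' @return a `genome_assembly`.
#' @export
read_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("parse error in ", path, ": empty file (line 1)")
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("parse error in ", path, ": expected FASTA header at line ", first)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("parse error in ", path, ": no records (line 1)")
  seqs <- as.character(set)
  # header names: keep first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(seqs, name = name)
}

#' Write a genome assembly to FASTA
#' @param genome a `genome_assembly`.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Extract a subsequence from an assembly
#'
#' Coordinates are internal 0-based half-open. For strand `"-"` the reverse
#' complement is returned.
#'
#' @param genome a `genome_assembly`.
#' @param chrom sequence name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return a nucleotide string.
#' @export
get_subsequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown sequence: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("invalid interval %s:[%d,%d) on sequence of length %d",
                 chrom, start, end, len))
  s <- substr(genome[[chrom]], start + 1, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

#' Reverse-complement a nucleotide string
#' @param sequence nucleotide string (ACGTN).
#' @return the reverse complement.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Assemble a probe set
#'
#' A probe set is a data frame of located oligos with one row per probe:
#' `id`, `chrom`, `start`, `end` (0-based half-open), `strand`, `sequence`,
#' `tm` (degrees Celsius) and `gc` (fraction). Rows are sorted by
#' (chrom, start). When a genome is supplied, missing sequences are extracted
#' from it and supplied sequences are validated against it.
#'
#' @param id,chrom,start,end,strand,sequence per-probe fields; `sequence`,
#'   `strand` optional.
#' @param genome optional `genome_assembly` for extraction/validation.
#' @param params `thermo_params` used for Tm computation.
#' @return a `probe_set` data frame.
#' @export
probe_set <- function(id, chrom, start, end, strand = "+", sequence = NA_character_,
                      genome = NULL, params = thermo_params()) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate probe id: ", df$id[duplicated(df$id)][1])
  if (any(df$start < 0 | df$start >= df$end))
    stop("invalid interval for probe ", df$id[df$start < 0 | df$start >= df$end][1])
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    bad <- !(df$chrom %in% names(lens)) | df$end > lens[df$chrom]
    if (any(bad))
      stop("interval outside chromosome for probe ", df$id[bad][1])
    for (i in seq_len(nrow(df))) {
      gs <- get_subsequence(genome, df$chrom[i], df$start[i], df$end[i], df$strand[i])
      if (is.na(df$sequence[i])) {
        df$sequence[i] <- gs
      } else if (!identical(toupper(df$sequence[i]), gs)) {
        stop("sequence disagrees with genome substring for probe ", df$id[i])
      }
    }
  }
  df$sequence <- toupper(df$sequence)
  ok <- !is.na(df$sequence) & !grepl("[^ACGT]", df$sequence) &
    nchar(df$sequence) >= 8
  df$gc <- ifelse(ok, vapply(df$sequence, function(s)
    if (is.na(s) || grepl("[^ACGT]", s)) NA_real_ else gc_content(s), 0.0), NA_real_)
  df$tm <- NA_real_
  if (any(ok)) df$tm[ok] <- melting_temperature(df$sequence[ok], params)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_set", "data.frame")
  df
}

#' Read probe definitions from TSV/BED
#'
#' Accepts a tab-delimited file with a header row containing at least
#' `id`, `chrom`, `start`, `end` and optionally `sequence` and `strand`, or a
#' headerless BED4 file (`chrom`, `start`, `end`, `id`). The coordinate
#' convention of a TSV is declared either by a `# coords=zero|one` comment
#' line or by the `coords` argument (default 1-based inclusive, the printed
#' convention); BED input is always 0-based half-open.
#'
#' @param path input path.
#' @param genome optional `genome_assembly`.
#' @param coords `"one"` (1-based inclusive) or `"zero"` (0-based half-open).
#' @param params `thermo_params`.
#' @return a `probe_set`, sorted by (chrom, start).
#' @export
read_probes <- function(path, genome = NULL, coords = c("one", "zero"),
                        params = thermo_params()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  decl <- grep("^#\\s*coords\\s*=", lines, value = TRUE)
  if (length(decl) > 0) {
    coords <- trimws(sub("^#\\s*coords\\s*=", "", decl[1]))
    coords <- match.arg(coords, c("one", "zero"))
  } else {
    coords <- match.arg(coords)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) stop("no probe rows in ", path)
  con <- textConnection(body)
  on.exit(close(con))
  has_header <- grepl("\\bid\\b", body[1]) || grepl("\\bchrom\\b", body[1])
  if (has_header) {
    df <- utils::read.delim(con, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  } else {
    df <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED input needs at least 4 columns")
    names(df)[1:4] <- c("chrom", "start", "end", "id")
    coords <- "zero"  # BED is 0-based half-open by definition
  }
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (coords == "one") start <- start - 1L
  probe_set(id = df$id, chrom = df$chrom, start = start, end = end,
            strand = if ("strand" %in% names(df)) df$strand else "+",
            sequence = if ("sequence" %in% names(df)) df$sequence else NA_character_,
            genome = genome, params = params)
}

#' Write a probe set as TSV (1-based inclusive coordinates)
#' @param probes a `probe_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  out <- data.frame(id = probes$id, chrom = probes$chrom,
                    start = probes$start + 1L, end = probes$end,
                    strand = probes$strand, sequence = probes$sequence,
                    tm = probes$tm, gc = probes$gc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coords=one", con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED4 (`chrom`, `start`, `end`, `gene`), 0-based half-open. Lines starting
#' with `#`, `track` or `browser` are skipped.
#'
#' @param path path to a BED file.
#' @return data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) stop("no gene rows in ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs 4 columns (chrom, start, end, name)")
  out <- data.frame(gene = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$start >= out$end))
    stop("invalid gene interval for ", out$gene[out$start < 0 | out$start >= out$end][1])
  out
}

#' Convert internal intervals to printed (1-based inclusive) form
#' @param start,end 0-based half-open coordinates.
#' @return data frame with `start` and `end` in 1-based inclusive form.
#' @export
to_printed_coords <- function(start, end) {
  data.frame(start = start + 1L, end = as.integer(end))
}

#' Convert printed (1-based inclusive) coordinates to internal form
#' @param start,end 1-based inclusive coordinates.
#' @return data frame with 0-based half-open `start` and `end`.
#' @export
from_printed_coords <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}
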