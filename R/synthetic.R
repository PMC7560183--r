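# Seeded synthetic-data generators for every input the toolkit consumes:
# template/target genome pairs with a known orthology map, tiled probe
# sets, CGH ratio tracks with piecewise-constant copy-number truth, and
# sex-mismatch X tracks with a balanced pseudoautosomal head. Each
# generator draws from R's RNG after seeding once at entry, so a fixed
# seed reproduces output byte-for-byte.

.seed_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Generate a random genome assembly
#'
#' @param lengths named vector of sequence lengths.
#' @param gc target GC fraction.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param name assembly label.
#' @return a `genome_assembly`.
#' @export
random_genome <- function(lengths, gc = 0.4, seed = NULL, name = "synthetic") {
  .seed_rng(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
  genome_assembly(seqs, name = name)
}

.OTHER_BASE <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

# mutate one locus sequence; returns list(sequence, n_sub, n_indel)
.mutate_locus <- function(seq, substitution_rate, indel_rate) {
  ch <- strsplit(seq, "")[[1]]
  sub_idx <- which(stats::runif(length(ch)) < substitution_rate)
  for (i in sub_idx)
    ch[i] <- sample(.OTHER_BASE[[ch[i]]], 1)
  ind_idx <- which(stats::runif(length(ch)) < indel_rate)
  # apply right-to-left so earlier positions stay valid
  for (i in rev(ind_idx)) {
    len <- stats::rgeom(1, 0.5) + 1
    if (stats::runif(1) < 0.5) {
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      ch <- append(ch, ins, after = i)
    } else {
      drop <- i:min(i + len - 1, length(ch))
      ch <- ch[-drop]
    }
  }
  list(sequence = paste(ch, collapse = ""),
       n_sub = length(sub_idx), n_indel = length(ind_idx))
}

#' Simulate a template/target genome pair with known orthology
#'
#' The template is a random assembly. It is tiled into loci of
#' `locus_length`; each retained locus becomes one scaffold of the target
#' assembly after divergence (uniform substitutions plus geometric-length
#' indels), emulating a draft assembly of unplaced scaffolds. A seeded
#' fraction of loci is deleted (no target scaffold) and another fraction
#' duplicated verbatim onto a second scaffold. The returned truth map
#' records each locus' fate and realized edit counts.
#'
#' @param chrom_lengths named vector of template chromosome lengths.
#' @param locus_length locus/scaffold size, bp.
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-base indel-event probability (geometric lengths,
#'   mean 2).
#' @param deleted_fraction,duplicated_fraction fractions of loci deleted /
#'   duplicated (exact seeded counts, rounded).
#' @param gc template GC fraction.
#' @param seed RNG seed.
#' @return list with `template`, `target` (both `genome_assembly`) and
#'   `truth` (data frame: `chrom`, `start`, `end` (0-based half-open
#'   template locus), `scaffold`, `scaffold2`, `status` in
#'   orthologous/deleted/duplicated, `n_sub`, `n_indel`).
#' @export
simulate_genome_pair <- function(chrom_lengths = c(chrT1 = 200000L),
                                 locus_length = 2000L,
                                 substitution_rate = 0.05,
                                 indel_rate = 0.002,
                                 deleted_fraction = 0.05,
                                 duplicated_fraction = 0.02,
                                 gc = 0.4, seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            deleted_fraction >= 0, deleted_fraction < 1,
            duplicated_fraction >= 0, duplicated_fraction < 1)
  .seed_rng(seed)
  template <- random_genome(chrom_lengths, gc = gc, seed = NULL,
                            name = "template")
  loci <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nl <- floor(chrom_lengths[[ch]] / locus_length)
    if (nl == 0) return(NULL)
    data.frame(chrom = ch,
               start = (seq_len(nl) - 1) * locus_length,
               end = seq_len(nl) * locus_length,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(loci)
  n_del <- round(deleted_fraction * n)
  n_dup <- round(duplicated_fraction * n)
  if (n_del + n_dup > n) stop("deleted and duplicated fractions leave no loci")
  pick <- sample(n, n_del + n_dup)
  loci$status <- "orthologous"
  loci$status[pick[seq_len(n_del)]] <- "deleted"
  if (n_dup > 0) loci$status[pick[n_del + seq_len(n_dup)]] <- "duplicated"
  if (all(loci$status == "deleted")) stop("all loci deleted; empty target")
  loci$scaffold <- NA_character_
  loci$scaffold2 <- NA_character_
  loci$n_sub <- 0L
  loci$n_indel <- 0L
  scaffolds <- list()
  sc <- 0
  for (i in seq_len(n)) {
    if (loci$status[i] == "deleted") next
    seq_i <- get_subsequence(template, loci$chrom[i], loci$start[i], loci$end[i])
    mut <- .mutate_locus(seq_i, substitution_rate, indel_rate)
    sc <- sc + 1
    nm <- sprintf("scaffold_%05d", sc)
    scaffolds[[nm]] <- mut$sequence
    loci$scaffold[i] <- nm
    loci$n_sub[i] <- mut$n_sub
    loci$n_indel[i] <- mut$n_indel
    if (loci$status[i] == "duplicated") {
      sc <- sc + 1
      nm2 <- sprintf("scaffold_%05d", sc)
      scaffolds[[nm2]] <- mut$sequence
      loci$scaffold2[i] <- nm2
    }
  }
  ord <- sample(length(scaffolds))
  target <- genome_assembly(unlist(scaffolds[ord]), name = "target")
  list(template = template, target = target, truth = loci)
}

#' Simulate a tiled probe set
#'
#' Probes are placed along each sequence at the target start-to-start
#' spacing with uniform jitter, skipping windows containing N; realized
#' mean spacing stays within ~10% of the target for 100 or more probes.
#'
#' @param genome a `genome_assembly`.
#' @param spacing target start-to-start spacing, bp.
#' @param probe_length probe length, nt.
#' @param jitter uniform jitter as a fraction of `spacing`.
#' @param seed RNG seed.
#' @param params `thermo_params` for Tm/GC annotation.
#' @return a `probe_set`.
#' @export
simulate_probes <- function(genome, spacing = 20000L, probe_length = 60L,
                            jitter = 0.25, seed = 1,
                            params = thermo_params()) {
  stopifnot(spacing > probe_length)
  .seed_rng(seed)
  lens <- seq_lengths(genome)
  rows <- list()
  k <- 0
  for (ch in names(lens)) {
    pos <- round(spacing / 2)
    while (pos + probe_length <= lens[[ch]]) {
      s <- get_subsequence(genome, ch, pos, pos + probe_length)
      if (!grepl("N", s, fixed = TRUE)) {
        k <- k + 1
        rows[[k]] <- data.frame(id = sprintf("probe_%06d", k), chrom = ch,
                                start = pos, end = pos + probe_length,
                                stringsAsFactors = FALSE)
      }
      step <- spacing * stats::runif(1, 1 - jitter, 1 + jitter)
      pos <- pos + round(step)
    }
  }
  if (k == 0) stop("genome too short for the requested spacing")
  df <- do.call(rbind, rows)
  probe_set(df$id, df$chrom, df$start, df$end, genome = genome, params = params)
}

#' Simulate a CGH ratio track over a probe grid
#'
#' Each probe's log2 ratio is the piecewise-constant truth level at its
#' position plus i.i.d. Gaussian noise. Truth level and state are recorded
#' per probe.
#'
#' @param probes data frame with `probe`/`id`, `chrom`, `pos`/`start`.
#' @param cna data frame of true aberrations (`chrom`, `start`, `end`
#'   0-based half-open, `log2`); positions outside any aberration have
#'   truth level 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param thresholds `cna_thresholds` used to record the truth state.
#' @return a `ratio_track` with extra columns `truth_log2`, `truth_state`.
#' @export
simulate_cgh <- function(probes, cna = NULL, noise_sd = 0.15, seed = 1,
                         thresholds = cna_thresholds()) {
  .seed_rng(seed)
  id <- if ("probe" %in% names(probes)) probes$probe else probes$id
  pos <- if ("pos" %in% names(probes)) probes$pos else probes$start
  chrom <- probes$chrom
  truth <- rep(0, length(pos))
  if (!is.null(cna) && nrow(cna) > 0) {
    for (i in seq_len(nrow(cna))) {
      sel <- chrom == cna$chrom[i] & pos >= cna$start[i] & pos < cna$end[i]
      truth[sel] <- cna$log2[i]
    }
  }
  vals <- truth + stats::rnorm(length(pos), 0, noise_sd)
  ratio_track(id, chrom, pos, vals,
              truth_log2 = truth,
              truth_state = classify_state(truth, thresholds))
}

#' Simulate a sex-mismatch hybridization track
#'
#' Emulates hybridizing female (two X copies) against male (one X copy)
#' DNA: X probes distal to the pseudoautosomal region sit at truth level
#' log2(2/1) = 1, PAR and autosomal probes at 0, plus Gaussian noise.
#' Optional autosomal aberrations can be embedded through `cna`.
#'
#' @param x_length X chromosome length, bp.
#' @param par_length PAR length from the p-terminus, bp.
#' @param autosome_lengths named vector of autosome lengths (`NULL` for an
#'   X-only track).
#' @param spacing probe spacing, bp.
#' @param noise_sd Gaussian noise sd.
#' @param cna optional autosomal aberrations (`chrom`, `start`, `end`,
#'   `log2`).
#' @param jitter spacing jitter fraction.
#' @param seed RNG seed.
#' @return list with `track` (a `ratio_track`; X labeled `"X"`) and
#'   `truth` (list: `par_interval` = c(0, par_length), `last_par_pos`,
#'   `first_x_pos`, `boundary_index`, `cna`).
#' @export
simulate_sex_mismatch <- function(x_length = 130557009, par_length = 7e6,
                                  autosome_lengths = c(A1 = 1e8, A2 = 8e7),
                                  spacing = 23000L, noise_sd = 0.15,
                                  cna = NULL, jitter = 0.25, seed = 1) {
  stopifnot(par_length < x_length)
  .seed_rng(seed)
  jpos <- function(len) {
    out <- numeric(0)
    pos <- round(spacing / 2)
    while (pos < len) {
      out <- c(out, pos)
      pos <- pos + round(spacing * stats::runif(1, 1 - jitter, 1 + jitter))
    }
    out
  }
  xpos <- jpos(x_length)
  truth_x <- ifelse(xpos < par_length, 0, 1)
  chrom <- rep("X", length(xpos))
  pos <- xpos
  truth <- truth_x
  if (!is.null(autosome_lengths)) {
    for (ch in names(autosome_lengths)) {
      ap <- jpos(autosome_lengths[[ch]])
      at <- rep(0, length(ap))
      if (!is.null(cna) && nrow(cna) > 0) {
        for (i in which(cna$chrom == ch))
          at[ap >= cna$start[i] & ap < cna$end[i]] <- cna$log2[i]
      }
      chrom <- c(chrom, rep(ch, length(ap)))
      pos <- c(pos, ap)
      truth <- c(truth, at)
    }
  }
  vals <- truth + stats::rnorm(length(pos), 0, noise_sd)
  track <- ratio_track(sprintf("probe_%06d", seq_along(pos)), chrom, pos, vals,
                       truth_log2 = truth)
  last_par <- if (any(xpos < par_length)) max(xpos[xpos < par_length]) else NA_real_
  first_x <- min(xpos[xpos >= par_length])
  list(track = track,
       truth = list(par_interval = c(0, par_length),
                    last_par_pos = last_par, first_x_pos = first_x,
                    boundary_index = sum(xpos < par_length),
                    cna = cna))
}
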