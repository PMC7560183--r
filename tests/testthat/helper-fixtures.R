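# shared fixtures: small deterministic sequences and genomes built in code

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# plant a (possibly mutated) copy of `insert` into a random background
plant_seq <- function(background, insert, at) {
  paste0(substr(background, 1, at - 1), insert,
         substr(background, at + nchar(insert), nchar(background)))
}

mutate_seq <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  idx <- which(runif(length(ch)) < rate)
  for (i in idx) ch[i] <- sample(other[[ch[i]]], 1)
  paste(ch, collapse = "")
}

# noise-free ratio track from run-length (level, n) pairs on one chromosome
rle_track <- function(levels, ns, chrom = "chr1", spacing = 20000) {
  vals <- rep(levels, ns)
  n <- length(vals)
  ratio_track(sprintf("p%04d", seq_len(n)), chrom,
              (seq_len(n) - 1) * spacing, vals)
}
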