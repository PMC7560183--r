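# Nearest-neighbor duplex thermodynamics (unified DNA/DNA parameter set of
# Allawi & SantaLucia 1997) with the entropy-based monovalent salt correction.
# dH in kcal/mol, dS in cal/(mol K).

.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.987  # cal/(mol K)

#' Thermodynamic matching parameters
#'
#' Tolerances and duplex-model settings used when matching a candidate probe
#' to a template probe's thermodynamic profile. The concentration defaults
#' (0.5 M Na+, 500 nM total strand) place typical 60-mers of 18-58% GC in
#' the 71-89 degree C range, with a 36% GC 60-mer near 80 degrees C, the
#' regime oligo array designs are matched in.
#'
#' @param tm_tolerance allowed |Tm difference| from the template, degrees C.
#' @param gc_tolerance allowed |GC difference| from the template, fraction.
#' @param min_len,max_len allowed probe length bounds, nt.
#' @param na_conc monovalent cation concentration, mol/L.
#' @param oligo_conc total strand concentration, mol/L.
#' @return an object of class `thermo_params`.
#' @export
thermo_params <- function(tm_tolerance = 2.0, gc_tolerance = 0.05,
                          min_len = 45L, max_len = 75L,
                          na_conc = 0.5, oligo_conc = 5e-7) {
  stopifnot(tm_tolerance > 0, gc_tolerance > 0,
            min_len < max_len, min_len >= 8,
            na_conc > 0, oligo_conc > 0)
  structure(list(tm_tolerance = tm_tolerance, gc_tolerance = gc_tolerance,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 na_conc = na_conc, oligo_conc = oligo_conc),
            class = "thermo_params")
}

.check_acgt <- function(sequence, min_len = 1L) {
  if (any(is.na(sequence)) || any(!nzchar(sequence)))
    stop("empty sequence")
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequence contains characters outside ACGT")
  if (any(nchar(sequence) < min_len))
    stop("sequence shorter than ", min_len, " nt")
}

#' GC content of a sequence
#' @param sequence nucleotide string(s), ACGT only.
#' @return fraction of G+C bases, in \[0, 1\]; vectorized.
#' @export
gc_content <- function(sequence) {
  sequence <- toupper(sequence)
  .check_acgt(sequence)
  vapply(strsplit(sequence, ""), function(ch) mean(ch %in% c("G", "C")), 0.0)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor parameter
#' set with initiation terms, the entropy salt correction
#' `dS + 0.368 (N-1) ln\[Na+\]`, and `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15`
#' for non-self-complementary duplexes.
#'
#' @param sequence nucleotide string(s), ACGT, length >= 8; vectorized.
#' @param params a `thermo_params`.
#' @return melting temperature(s) in degrees Celsius.
#' @export
melting_temperature <- function(sequence, params = thermo_params()) {
  sequence <- toupper(sequence)
  .check_acgt(sequence, min_len = 8L)
  vapply(sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    nn <- paste0(ch[-length(ch)], ch[-1])
    dH <- .INIT_DH[[ch[1]]] + .INIT_DH[[ch[length(ch)]]] + sum(.NN_DH[nn])
    dS <- .INIT_DS[[ch[1]]] + .INIT_DS[[ch[length(ch)]]] + sum(.NN_DS[nn]) +
      0.368 * (length(ch) - 1) * log(params$na_conc)
    1000 * dH / (dS + .GAS_R * log(params$oligo_conc / 4)) - 273.15
  }, 0.0, USE.NAMES = FALSE)
}

# Cumulative nearest-neighbor profile of a context string, allowing O(1)
# Tm/GC evaluation of any window. Positions with N poison overlapping windows.
.thermo_profile <- function(context) {
  ch <- strsplit(context, "")[[1]]
  n <- length(ch)
  isn <- ch == "N"
  nn <- paste0(ch[-n], ch[-1])
  known <- nn %in% names(.NN_DH)
  dh <- ifelse(known, .NN_DH[nn], 0)
  ds <- ifelse(known, .NN_DS[nn], 0)
  list(n = n,
       cumH = c(0, cumsum(dh)), cumS = c(0, cumsum(ds)),
       cumGC = c(0, cumsum(ch %in% c("G", "C"))),
       cumN = c(0, cumsum(isn)),
       initH = ifelse(isn, NA_real_, .INIT_DH[ch]),
       initS = ifelse(isn, NA_real_, .INIT_DS[ch]))
}

# Vectorized Tm/GC of windows [starts, ends] (1-based inclusive in context).
.window_thermo <- function(prof, starts, ends, params) {
  len <- ends - starts + 1
  nN <- prof$cumN[ends + 1] - prof$cumN[starts]
  dH <- prof$initH[starts] + prof$initH[ends] +
    (prof$cumH[ends] - prof$cumH[starts])
  dS <- prof$initS[starts] + prof$initS[ends] +
    (prof$cumS[ends] - prof$cumS[starts]) +
    0.368 * (len - 1) * log(params$na_conc)
  tm <- 1000 * dH / (dS + .GAS_R * log(params$oligo_conc / 4)) - 273.15
  gc <- (prof$cumGC[ends + 1] - prof$cumGC[starts]) / len
  tm[nN > 0] <- NA_real_
  gc[nN > 0] <- NA_real_
  list(tm = tm, gc = gc)
}

#' Adjust probe boundaries to match a template thermodynamic profile
#'
#' Searches all windows of the supplied context that overlap the candidate
#' core and lie within the configured length bounds, for one whose melting
#' temperature and GC content fall within tolerance of the template probe's.
#' Among feasible windows the one minimizing |Tm difference| is chosen,
#' ties broken by |GC difference|, then by minimal positional shift from the
#' core, then by leftmost start and shortest length (deterministic).
#'
#' @param context flanking target sequence containing the core.
#' @param core_start,core_end 1-based inclusive position of the core within
#'   `context`.
#' @param template_tm,template_gc thermodynamic profile to match.
#' @param params a `thermo_params`.
#' @return list with `status` (`"adjusted"`, `"unchanged"` or
#'   `"failed_adjust"`) and, on success, `start`, `end` (1-based in context),
#'   `sequence`, `tm`, `gc`.
#' @export
adjust_probe <- function(context, core_start, core_end, template_tm,
                         template_gc, params = thermo_params()) {
  context <- toupper(context)
  nc <- nchar(context)
  if (core_start < 1 || core_end > nc || core_start > core_end)
    stop("core does not lie within context")
  prof <- .thermo_profile(context)

  # core itself first: returned unchanged when already within both tolerances
  core_len <- core_end - core_start + 1
  if (core_len >= params$min_len && core_len <= params$max_len) {
    wt <- .window_thermo(prof, core_start, core_end, params)
    if (!is.na(wt$tm) &&
        abs(wt$tm - template_tm) <= params$tm_tolerance &&
        abs(wt$gc - template_gc) <= params$gc_tolerance) {
      return(list(status = "unchanged", start = core_start, end = core_end,
                  sequence = substr(context, core_start, core_end),
                  tm = wt$tm, gc = wt$gc))
    }
  }

  grid <- expand.grid(start = seq_len(nc),
                      len = params$min_len:params$max_len)
  grid$end <- grid$start + grid$len - 1
  grid <- grid[grid$end <= nc &
                 grid$start <= core_end & grid$end >= core_start, , drop = FALSE]
  if (nrow(grid) == 0) return(list(status = "failed_adjust"))
  wt <- .window_thermo(prof, grid$start, grid$end, params)
  feas <- !is.na(wt$tm) &
    abs(wt$tm - template_tm) <= params$tm_tolerance &
    abs(wt$gc - template_gc) <= params$gc_tolerance
  if (!any(feas)) return(list(status = "failed_adjust"))
  g <- grid[feas, , drop = FALSE]
  dtm <- abs(wt$tm[feas] - template_tm)
  dgc <- abs(wt$gc[feas] - template_gc)
  shift <- abs(g$start - core_start) + abs(g$end - core_end)
  ord <- order(dtm, dgc, shift, g$start, g$len)
  i <- ord[1]
  list(status = "adjusted", start = g$start[i], end = g$end[i],
       sequence = substr(context, g$start[i], g$end[i]),
       tm = wt$tm[feas][i], gc = wt$gc[feas][i])
}
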