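---
title: "Methods: cross-species probe migration and aCGH copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species probe migration and aCGH copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghlift)
```

# Overview

`cghlift` implements two connected workflows around oligonucleotide
array comparative genomic hybridization (oaCGH):

1. **Probe migration** — transferring a well-characterized oligo probe
   design from a template genome (for example, a mature dog array
   design) to the orthologous loci of a target genome (for example, a
   draft cat assembly of unplaced scaffolds), preserving each probe's
   thermodynamic profile so the migrated design hybridizes uniformly.
2. **Copy-number analysis** — segmentation and state calling of log2
   tumor:reference ratio tracks, probe-spacing design QC,
   sex-mismatch/pseudoautosomal-boundary analysis, and paired-profile
   comparison.

This vignette records the models, parameter choices and numerical
conventions behind each module, including design decisions that were
genuinely open.

# Coordinate conventions

Internally every interval is 0-based half-open, which makes length and
overlap arithmetic exact (`length = end - start`, overlap iff
`start_a < end_b && start_b < end_a`). All file I/O and printed reports
use 1-based inclusive coordinates, the convention of genome browsers
and the array literature; the conversion happens only at the I/O
boundary (`to_printed_coords()`, `from_printed_coords()`). Probe
tracks store positions as probe start offsets; segment boundaries are
the positions of their first and last probes.

# Thermodynamic model

Melting temperatures use nearest-neighbor thermodynamics with the
unified DNA/DNA parameter set (Allawi & SantaLucia 1997), initiation
terms for the duplex termini, the entropy-based monovalent salt
correction `dS' = dS + 0.368 (N-1) ln[Na+]`, and

```
Tm (deg C) = 1000 dH / (dS' + R ln(Ct/4)) - 273.15
```

for non-self-complementary duplexes at total strand concentration
`Ct`. The defaults — 0.5 M Na+ and 500 nM total strand — were chosen
so that typical 60-mers score in the regime oligo array designs are
matched in: a 36% GC 60-mer scores near 80 °C and the 18–58% GC range
spans roughly 72–89 °C. Both concentrations are configurable through
`thermo_params()`. Because every nearest-neighbor pair and terminal
initiation parameter is symmetric under reverse complement, Tm and GC
are strand-invariant, so template probes can be treated as plus-strand
sequences without loss of generality.

**Boundary adjustment.** "Consistent with" the template probe's
profile is operationalized as |ΔTm| ≤ 2 °C and |ΔGC| ≤ 5 percentage
points (both configurable). `adjust_probe()` enumerates every window
of the available target context that overlaps the orthologous core and
lies within the length bounds (default 45–75 nt around the nominal
~60-mer), evaluating each in O(1) from cumulative nearest-neighbor
sums. Among feasible windows it minimizes |ΔTm|, breaking ties by
|ΔGC|, then by minimal positional shift from the core (preserving
orthologous centering), then leftmost-shortest for determinism. A core
already within both tolerances is returned unchanged. Windows
containing N are rejected: the design contract is unique, repeat-free
probes, so ambiguous bases disqualify a candidate rather than being
scored.

# Alignment engine

Ortholog search uses a self-contained k-mer seeded local aligner
(default k = 11): exact seed matches are clustered by diagonal, each
candidate window is aligned by full affine-gap Smith–Waterman
(Gotoh; gap of length L costs `gap_open + L*gap_ext`, defaults
match +1 / mismatch −2 / open 2 / extend 1), and hits are reported
with their aligned-column maps. On sequences where the full dynamic
program is tractable the seeded search returns the same optimal score
— the test suite verifies this against an independent Smith–Waterman
implementation. The scoring interface is pluggable via
`align_params()`, so an external aligner could substitute behind
`find_ortholog()`.

A hit is *robust* when its identity is ≥ 0.75 over at least half of
the extended query, and *unambiguous* when its score exceeds the best
score at any distinct locus by a factor of 1.1. These thresholds are
explicit configuration, not a claim about any historical pipeline;
they are logged in the migration records.

# Migration cascade

For each template probe: extend with 100 nt of flanking template
sequence (a 60-mer becomes a ~260-nt query, clipped at chromosome
ends); search all target sequences; extract the target core by
replaying the aligned-column map over the core columns (gap columns
dropped; fail below 80% aligned core columns); then classify —

* `exact_match` — target core identical to the template probe;
* `direct_ortholog` — core meets both tolerances unadjusted;
* `adjusted` — a boundary-adjusted window meets them;
* `failed_adjust` — no window qualifies (the nucleotide composition of
  the available target sequence precludes a matched probe);
* `no_alignment` / `ambiguous_map` — search-stage failures.

A final uniqueness pass (`verify_unique()`) demotes any candidate to
`ambiguous_map` unless exactly one target locus matches it at ≥ 90%
of its full length. The exact-match class is defined over the probe
core, not the extended query. The ledger preserves both the cascade
("stage") classes and the final statuses, so the accounting identities
hold: `no_alignment + candidates + failed_adjust = total`,
`candidates = exact + direct + adjusted`, and
`final = candidates - ambiguous_map`.

# Design QC

Spacing is start-to-start between consecutive probes — this makes mean
spacing ≈ chromosome span / (N−1) and matches per-chromosome design
summary tables. Quartiles default to R's type-7 (linear interpolation)
rule; the boxplot outlier rule is strict: intervals > Q3 + 1.5·IQR.
Coverage fractions are strictly-below counts. The totals row of a
per-chromosome summary table uses *unweighted* means of the
per-chromosome mean spacings and probes/Mb — `summary_table_totals()`
reproduces the published feline design's totals row (110,456 probes;
2,460,251,910 bp; 22,631 bp; 44 probes/Mb) from its per-chromosome
rows — while `genome_spacing_report()` also reports pooled
(interval-weighted) variants, which differ when chromosomes are
unevenly covered.

# Segmentation and calling

The published analysis this mirrors used a proprietary segmentation
algorithm; `cghlift` substitutes an open, named strategy while keeping
the calling contract identical. Segmentation is least-squares binary
segmentation per chromosome: the split maximizing the reduction in the
residual sum of squares is accepted when the reduction exceeds
`penalty_mult * sigma^2 * log(n)` (default multiplier 3), with sigma
estimated robustly as `mad(diff(x))/sqrt(2)`. On noise-free
piecewise-constant tracks sigma is 0 and changepoints are recovered
exactly, while a constant track yields no split.

Calling applies the thresholds as printed, inclusively: gain ≥ 0.201,
loss ≤ −0.234, high-amplitude ≥ 1.14 / ≤ −1.1 (high takes
precedence), with a minimum window of three consecutive probes.
Sub-minimum segments are merged into the flanking segment with the
closer mean (ties to the left), so a 2-probe excursion can never be
called regardless of amplitude. Chromosomes are segmented
independently. Gene overlap is half-open with a 1 bp minimum — a gene
abutting a segment boundary is not reported.

# Sex-mismatch analysis

In a female-vs-male hybridization the X-specific region sits at a
theoretical log2 ratio of `log2(2/1) = 1` and autosomes at 0; the
pseudoautosomal region (PAR), shared by X and Y, appears balanced.
`chromosome_mean()` supports excluding the PAR interval when
summarizing X. `detect_par_boundary()` scans the ordered X track for
the first run of at least `k = 3` consecutive probes at or above the
gain threshold that *persists* — at least 80% of the next 20 probes
also gained. The persistence guard is needed because with realistic
noise (sd 0.15) a spurious triple above 0.201 occurs somewhere in a
~300-probe balanced head in a substantial fraction of experiments;
requiring local persistence rejects those without moving the detected
boundary, since the genuine transition is followed by essentially
all-gained probes. The boundary is reported as the open window between
the last balanced probe and the first probe of the sustained run —
a window, not a point estimate, because probe spacing limits
resolution; a coarse containing interval is also available at the
segment level via `segment_track()`.

# Profile comparison

`compare_profiles()` works on the shared probe grid rather than base
pairs, so unequal segment boundaries need no interval algebra:
each probe gets its state under both segmentations, concordance is the
(optionally bp-weighted) fraction of compared probes with identical
state, and discordant regions are maximal runs with a constant state
pair, each annotated with the mean difference of segment means.
States compare at five levels by default; `levels = "three"` collapses
high-amplitude states for a qualitative gain/loss reading.

# Synthetic data

The generators emit exactly the formats the analysis consumes, so the
whole pipeline is testable offline; all are deterministic under a
fixed seed.

* `simulate_genome_pair()` tiles a random template into 2 kb loci and
  emits each retained locus as one target scaffold after divergence —
  uniform substitutions (default 5%), indel events (default 0.002/bp,
  geometric lengths of mean 2), an exact seeded count of deleted loci
  and of verbatim-duplicated loci (two scaffolds). This emulates
  migrating a design into a fragmented draft assembly of unplaced
  scaffolds; no transition/transversion bias is modeled, as it is
  irrelevant to alignment recovery at this scale.
* `simulate_probes()` tiles probes at a target spacing with ±25%
  uniform jitter, skipping N windows (realized mean spacing within
  ~10% of target).
* `simulate_cgh()` adds i.i.d. Gaussian noise (default sd 0.15) to a
  piecewise-constant truth; real array noise is heavier-tailed and
  locally correlated (waves), so passing tests demonstrate the
  calling contract, not robustness to wave artefacts.
* `simulate_sex_mismatch()` defaults emulate the validation
  experiment's conditions: a 130.56 Mb X with a 7 Mb PAR head, 23 kb
  probe spacing, two autosomes (100/80 Mb), noise sd 0.15.

# Problem sizes used in the tests

The suite exercises migration on a 100–120 kb template (50–60 loci of
2 kb, one probe per locus), alignment equivalence on ≤ 2 kb subjects,
PAR-boundary recovery on 100 replicates of a 15 Mb X at 23 kb spacing,
and segment-mean recovery at 80 probes per segment over five states
(−2.5, −0.5, 0, +0.3, +1.5; sd 0.15). These sizes exercise every
code path at full fidelity while keeping the default test run fast.

# Known limitations

* Repeat masking is the caller's responsibility; there is no built-in
  repeat library (template probe sets are assumed pre-masked).
* No secondary-structure or cross-hybridization screening.
* Segmentation assumes independent Gaussian-ish noise; no wave
  correction or recentering beyond the autosomal-median option.
* Uniqueness checking counts seeded near-matches; two near-identical
  loci closer than one query length on the same scaffold can collapse
  into one reported locus.
* No allele-specific copy number, purity/ploidy deconvolution, or
  cohort-level recurrence analysis.
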