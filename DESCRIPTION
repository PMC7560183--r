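Package: cghlift
Title: Cross-Species Oligonucleotide Probe Migration and Array-CGH Copy
    Number Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for migrating oligonucleotide array probes from a
    well-characterized template genome to the orthologous loci of a target
    genome with thermodynamic (melting temperature and GC content) matching,
    and for downstream array comparative genomic hybridization (aCGH)
    analysis: log2-ratio computation, probe QC filtering, least-squares
    segmentation with threshold-based copy-number calling, probe-spacing
    design QC, sex-mismatch and pseudoautosomal-boundary analysis, and
    paired tumor-profile comparison. Includes seeded synthetic-data
    generators (diverged genome pairs with known orthology, tiled probe
    sets, piecewise-constant ratio tracks) so every pipeline stage can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
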