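Package: phascreen
Title: Screening and False-Positive Diagnostics for Phased Small RNA (PHAS) Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects phased secondary siRNA (phasiRNA) producing loci in
    small RNA-seq alignments and diagnoses the heterochromatic-siRNA false
    positives that plague 24-nt PHAS annotation. Implements three per-locus
    phasing statistics (a log-odds phasing score, a hypergeometric
    phasing p-value, and a phased-ratio score), positive-control-calibrated
    cutoffs, multi-library multi-algorithm consensus calling, phase-register
    consistency diagnostics, locus-property comparisons against random
    cohorts, mismatch-tolerant mature-miRNA homolog scanning with a hairpin
    plausibility check, and Allen-score small RNA target prediction. A
    ground-truthed synthetic small RNA data generator emulates true PHAS
    loci and heterochromatic siRNA loci so the whole screen is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
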