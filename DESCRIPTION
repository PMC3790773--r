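Package: exopair
Title: Coupled Copy-Number and Allelic-Imbalance Calling from Matched Exome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy-number alterations (CNA) and loss-of-heterozygosity /
    allelic-imbalance (LOH/AI) events from case-control matched whole-exome
    sequencing coverage. Per-exon case and control depths are extracted from
    pileup, SAM or BAM input against a BED-like exon database, median-normalized,
    and segmented with a matched-pairs Wilcoxon signed-rank test (exact
    enumeration at small n, continuity-corrected normal approximation with a
    polynomial error-function otherwise) using a seed/expand/merge strategy and
    a configurable filter stack. Control-heterozygous positions are called with
    an exact binomial goodness-of-fit test, re-tested in the case, and
    classified into copy loss, copy-neutral LOH and one- or multi-copy gains by
    normalized coverage fold. A deterministic exome simulator generates paired
    coverage and allele-count tables with known truth, and a scoring harness
    measures sensitivity, positive predictive value and hypersegmentation under
    a region-overlap criterion. Tabular, Circos and static plot exports are
    included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
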