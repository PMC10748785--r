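Package: varbench
Title: Small-Variant Benchmarking with Harmonization, Pileup Re-Check and
    Threshold Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarks a small-variant callset against a ground-truth callset
    inside high-confidence regions. Variants from both callsets are harmonized
    into a single canonical representation (multi-allelic decomposition,
    left-alignment, parsimony) so that divergent spellings of the same edit
    never inflate the error counts. Standard accuracy metrics (recall,
    precision, specificity, F1, FDR) are complemented by the maximum
    theoretical recall, obtained by re-checking every false negative in the
    read evidence (BAM/SAM or a readcount table) and splitting false negatives
    into bioinformatic (supporting reads present) and sequencing (no support)
    classes. A parameter-analysis stage compares quality-parameter
    distributions across call classes, builds per-parameter ROC curves on the
    sequencing-positive set, derives optimal cutpoints, and simulates the
    accuracy obtained under new caller thresholds. A deterministic synthetic
    generator produces complete benchmark fixtures (reference, truth and query
    VCFs, BED, reads) with ground-truth labels for every error class.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
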