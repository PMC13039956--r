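Package: svfold
Title: Screening Structural Variants for Disruption of 3D Genome Folding
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico mutagenesis screen for somatic structural variants
    (SVs) that disrupt chromatin contact maps. For each deletion, duplication,
    inversion, insertion or breakend call the package builds length-matched
    reference and alternate sequences over a ~1 Mb prediction window (with -1
    bp, +1 bp and reverse-complement augmentations), obtains predicted contact
    maps from a pluggable predictor, and scores the disruption as the mean
    squared error and one-minus-Pearson-correlation between the two maps
    outside the masked variant region. Downstream stages weight disruption by
    Activity-by-Contact enhancer activity (geometric mean of ATAC and H3K27ac
    read counts), discover recurrently disrupted 1 Mb regions across a tumor
    cohort, and run the cohort-level statistics (initial versus progressive
    burden tests, disruption-cutoff calibration, disrupted-gene annotation,
    regulatory-peak enrichment, expression extremity, breakpoint confidence
    intervals and repeat concordance). A deterministic mechanistic toy
    predictor with motif-encoded domain boundaries and loop anchors, plus a
    full synthetic-study generator, make every stage testable without trained
    model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
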