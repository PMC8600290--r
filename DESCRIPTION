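Package: dyneQTL
Title: Environment-Aware eQTL Mapping of Gene Expression Dynamics in
    Segment Substitution Line Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies expression quantitative trait loci (eQTLs) that
    alter gene expression dynamics under fluctuating field conditions.
    Per-parent expression models are fitted from sparse time-series
    RNA-seq using circadian clock terms, a developmental (scaled age)
    term and gated-window meteorological features; simple sequence
    repeat markers are scanned across a chromosome segment substitution
    line (CSSL) panel for genotype-dependent reductions in weighted
    prediction error; eQTLs are called with permutation-calibrated
    false discovery rate control, classified as cis or trans, and
    validated by prediction in unseen environments and in mosaic-genome
    backcross-inbred lines. A synthetic-data generator emulates the
    full experimental design (reciprocal CSSL panel, staggered
    transplant sets, bihourly sampling days, diurnal and seasonal
    weather) for benchmarking and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
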