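Package: trialpatch
Title: Exact Phase 2 Design Statistics and HER2 Whole-Slide Patch Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translational analysis toolkit for single-arm anti-HER2
    antibody-drug-conjugate trials. Implements exact binomial single-stage
    (A'Hern) design search and two-stage rule evaluation, Clopper-Pearson
    response-rate intervals, a whole-slide HER2 immunohistochemistry patch
    pipeline (tissue detection by Law's spot texture energy, 64 px patch
    extraction, stain-deconvolution descriptors, mini-batch k-means with
    Davies-Bouldin model selection, per-slide cluster-proportion profiles and
    Mann-Whitney/Benjamini-Hochberg association), classical nuclei
    morphometrics (optical-density unmixing, watershed segmentation,
    deduplication and per-patch summaries), paired-biopsy genomic
    post-calling rules (coverage-dependent mutation rescue, unmatched
    germline discard, focal copy-number filtering with two-run
    reconciliation, acquired-alteration calling), multiplex
    immunofluorescence microenvironment statistics, and seeded synthetic-data
    generators with ground truth for offline verification of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    igraph,
    mgcv,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    tiff,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
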