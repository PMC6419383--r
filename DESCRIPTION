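Package: methworks
Title: Modular DNA Methylation Analysis at Single-CpG Resolution
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modular toolkit for quantitative DNA methylation analysis at
    single-CpG resolution, covering ingestion of bisulfite-sequencing
    methylation calls (Bismark coverage files, bedGraph) and tabular
    beta-value matrices, site filtering and missing-value imputation,
    aggregation of CpG-level methylation across genomic region sets,
    methylation-based inference of donor covariates (epigenetic age, sex,
    genetic noise, tumor purity, and reference-based cell-type composition),
    differential methylation and differential variability testing with
    worst-rank scoring, cross-platform dataset merging on shared CpGs,
    principal-component exploration, and Fisher-exact region-set enrichment.
    A seeded synthetic-cohort generator with recorded ground truth makes
    every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
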