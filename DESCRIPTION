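Package: ewasmeta
Title: Multi-Cohort EWAS Meta-Analysis Pipeline with Synthetic Consortium Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coordinated-consortium pipeline for epigenome-wide association
    studies (EWAS) of parental exposures and offspring blood DNA methylation:
    cohort-level per-CpG linear models with reference-based cell-type
    deconvolution and surrogate-variable adjustment, probe harmonization
    across Illumina 450k/EPIC arrays, inverse-variance fixed-effects
    meta-analysis with heterogeneity statistics and genomic inflation
    diagnostics, leave-one-out stability criteria, meta-regression and
    sensitivity subsets, and candidate-set enrichment tests. Includes a
    synthetic multi-cohort data generator with known ground truth (cell
    mixtures, latent batch structure, correlated parental exposures,
    injectable CpG effects) so every stage is testable without access to
    individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
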