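Package: senescape
Title: Chromatin, Metabolite and Single-Cell Statistics for Replicative
    Senescence Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for multiomic dissection of replicative
    senescence in serially passaged fibroblast cultures. Provides chromatin-state
    accounting for ATAC-seq peaks (state assignment, signal fractions, quantile
    normalisation, FRiP trends), permutation overlap tests against
    nucleolar/lamin-associated domains with expression-matched null sampling,
    motif enrichment and a ridge-logistic model scoring transcription-factor
    motifs for accessibility change, per-feature linear trend testing over
    population doubling level (PDL) with paired-control batch correction for
    metabolite panels, single-cell senescence-signature scoring with pseudobulk
    aggregation, and pseudotime trajectory smoothing with K-median cosine
    clustering. A synthetic-data module generates fixtures with the statistical
    structure these analyses assume, so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
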