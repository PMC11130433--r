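Package: tempoqtl
Title: Longitudinal Phenomics and Multi-Locus Mixed-Model GWAS for
    Transient QTL Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving daily growth traits from image-based
    phenotyping measurements (area, biomass, height, hull area, water use
    efficiency, relative growth rate), quality control by median-absolute-
    deviation outlier filtering and loess smoothing, per-day broad-sense
    heritability from replicated designs, temporal trait-profile
    clustering and ideotype classification, a multi-locus mixed-model
    (MLMM) association engine with pseudo-heritability stopping and
    multiple-Bonferroni / extended-BIC model selection, assembly of
    time-resolved (transient) QTL tracks, and candidate-gene window
    scans against GFF3 annotation. Includes a synthetic-data generator
    emulating structured inbred genotypes and temperature-phased logistic
    growth with planted transient QTL, for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
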