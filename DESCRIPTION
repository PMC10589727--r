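Package: peakAtlas
Title: Consensus Atlases of Intergenic RNA Polymerase II Binding and
    Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an atlas of intergenic consensus regions from many
    RNA polymerase II ChIP-seq peak sets by segmenting a Gaussian-smoothed
    summit density at its local minima, and provides the downstream
    machinery to mine transcription at those regions: intergenic peak
    filtering, binary occupancy matrices, biotype contribution scores and
    Gini-Simpson diversity, binomial and hypergeometric overlap
    enrichment, regularized negative-binomial Pearson-residual count
    transformation with detectability-restricted pooling size factors,
    chi-square highly-variable-region selection, Horn's parallel analysis,
    SNN-Leiden and three-step hierarchical clustering, per-biotype marker
    calling, Yule-distance meta-clustering across data sources,
    resampling-based pan-cancer marker thresholds, GREAT-style regulatory
    domains with negative-binomial gene-set enrichment, and per-region Cox
    survival screening with maximally selected log-rank cutpoints. A
    synthetic-data module generates peak sets, annotations, count matrices
    and survival tables with the statistical structure the analysis
    assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    matrixStats,
    igraph,
    survival,
    MASS,
    scran,
    uwot,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    RANN,
    withr
Config/testthat/edition: 3
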