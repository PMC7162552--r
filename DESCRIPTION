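Package: magicr
Title: Transcription Factor and Cofactor Enrichment from Continuous ChIP-Seq Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the MAGIC approach to predicting transcription factors
    and cofactors that drive gene-expression changes. Instead of binarizing
    genes into targets and non-targets, each Factor's full distribution of
    ChIP-seq peak signals over a gene universe is compared between a query
    gene list and its background list with an empirical-CDF sup-difference
    statistic, a Kolmogorov-Smirnov p-value, Benjamini-Hochberg correction,
    and a tail-enrichment ratio combined into a ranking Score. Includes the
    matrix-building pipeline from ENCODE-style narrowPeak files, the full
    tabular/GMX/figure output surface, a ranked-prediction evaluation module
    (precision-recall, ROC, rank-cumulative analysis against protein-link
    derived positive classes), and a synthetic-data generator with planted
    enrichment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
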