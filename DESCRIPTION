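Package: dauerclock
Title: Transcriptomic Aging Clocks and Time-Course Analysis for Dauer Diapause RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq time courses of C. elegans dauer
    diapause and dauer exit. Implements a binarized-transcriptome biological
    age clock (per-sample median binarization, elastic-net training on
    lifespan-rescaled age labels, coefficient-sum prediction, and an aging-rate
    statistic), a stochastic-data based clock score, per-gene linear trend
    differential expression on log-normalized counts with k-means trajectory
    clustering and elbow selection, hypergeometric gene-set over-representation
    against GMT collections, and a gene-length-dependent transcription decline
    (GLTD) test comparing length distributions of up- and down-regulated genes.
    A negative-binomial count simulator with age-monotone, transient,
    oscillatory and drift gene programs, lifespan-labeled cohorts and
    UV-dose-by-gene-length transcription-block effects provides ground-truth
    fixtures, and a pipeline driver orchestrates all stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
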