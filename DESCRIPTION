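Package: chipcourse
Title: Induction-Time Analysis of Time-Course ChIP-seq and TSS-seq Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies time-series ChIP-seq and TSS-seq signals at promoters
    and enhancers and calls significant stimulus-induced increases and their
    induction times without replicates. Peak calls are thresholded against
    control-swap calls at a fixed empirical FDR, merged across time points,
    corrected for whole-cell-extract background, converted to
    quantile-normalized reads-per-million values, and tested with a
    mean-dispersion-trend Z-score model: per-region dispersion (squared
    coefficient of variation over the time course) is regressed on median
    signal with a quadratic log-log fit, and deviations from the 0 h baseline
    are scored in units of the trend-implied standard deviation. Also
    includes a scanning-window TSS caller with a randomized null, promoter
    and enhancer definition, transcription-factor binding association
    (overlap enrichment, binding-site metaprofiles, timing curves), and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    limma,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
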