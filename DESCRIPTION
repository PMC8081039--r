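Package: wormdev
Title: Quantitative Phenotyping and Molecular Profiling of C. elegans Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based body-length morphometry (threshold, skeletonize,
    geodesic path length), logistic growth-curve fitting, windowed bootstrap
    length-ratio comparisons, Gardner-Altman style bootstrap estimation
    statistics, negative-binomial differential expression with
    median-of-ratios (pseudoreference) normalization and a local-regression
    dispersion trend, projection of transcriptomes onto a reference
    developmental time course, and a lipidomics filter/normalize/test
    pipeline. Every input class can be simulated with known ground truth, so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
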