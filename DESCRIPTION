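Package: mirpair
Title: Statistical Detection of miRNA-mRNA Expression Relationships in
    Matched Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects microRNA (miRNA) to messenger RNA (mRNA) regulatory
    relationships from matched expression profiles. Part 1 fits per-pair
    univariate, multivariate or interaction regressions under five
    distribution families (Gaussian, Poisson, negative binomial,
    zero-inflated Poisson, zero-inflated negative binomial) with
    AIC-based multi-model selection. Part 2 correlates miRNA and mRNA
    log2 fold-change vectors across three or more comparisons against a
    resampled background null. Part 3 tests a two-timepoint
    interrelation statistic (the absolute difference of fold changes)
    against a resampled null and classifies regulation type by sign
    pattern. Results can be filtered against miRanda- or
    TargetScan-style target-prediction scores. Includes a synthetic-data
    generator with planted ground truth for every statistical path and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    glmmTMB,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
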