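Package: radnorm
Title: MaxRank Normalization and Quantitative Comparison of Rank Abundance Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparison of abundance structures of
    generalized communities (microbiome OTU tables, B-cell receptor
    repertoires, and other assemblages of genetically diverse entities).
    Rank abundance distributions (RADs) of different richness are mapped by
    MaxRank normalization -- repeated subsampling of individuals without
    replacement up to a common maximum rank R -- to normalized RADs (NRADs)
    of identical dimension that can be compared directly. Downstream tools
    include Manhattan distances between NRADs, Shannon entropy and evenness,
    broken-stick and geometric reference models, classical multidimensional
    scaling, complete-linkage clustering, group averaging with bootstrap
    confidence intervals, random-forest classification with Cohen's kappa
    evaluation, an exponential-saturation model of entropy versus age, and a
    synthetic community generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    minpack.lm,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
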