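Package: maxhab
Title: Presence-Only Maximum-Entropy Habitat Modeling with AICc Variable
    Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end presence-only ecological niche modeling
    pipeline for gridded landscapes: spatial thinning of occurrence
    records by overlapping home-range buffers, an L1-regularized
    maximum-entropy habitat suitability model with linear, quadratic,
    product, hinge and categorical features, stepwise variable
    elimination scored by the sample-size-corrected Akaike information
    criterion (AICc), replicated bootstrap evaluation with AUC,
    maximized Cohen's kappa and the true skill statistic (TSS),
    max-TSS binary habitat mapping, zonal and protected-area gap
    summaries, patch fragmentation statistics, and a synthetic
    landscape generator with planted true responses for validating the
    whole pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
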