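Package: scalediv
Title: Multi-Taxon Diversity Scaling Across Nested Spatial Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-taxon diversity scaling in
    non-contiguous plot designs: permutation and analytic species
    accumulation curves, multimodel species-area fitting (eight
    asymptotic and non-asymptotic forms) with AICc selection and
    residual validation, richness extrapolation with plot-level
    bootstrap confidence bands, additive alpha/beta diversity
    partitioning across nested area scales, cross-taxon congruence
    statistics, abundance-based sample-coverage estimation over plot
    combinations, and a metacommunity simulator with tunable spatial
    turnover for ground-truth validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
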