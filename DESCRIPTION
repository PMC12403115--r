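Package: phenowood
Title: Phenological Metric Extraction and Cross-Trophic Comparison for
    Temperate Woodlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts comparable phenological metrics from multi-method
    field monitoring of deciduous trees and their caterpillar communities:
    half-dates from sigmoidal trajectories (bud scores, leaf area index,
    crown NDVI, cumulative frass and caterpillar capture) via Beta-family
    logit-link penalized-spline fits, and peak dates and heights from
    Poisson-family count-intensity fits. Provides absolute-agreement
    intraclass correlation for paired field measures, Spearman correlation
    matrices, Gaussian and Beta-likelihood regression models linking tree
    phenology to caterpillar phenology and herbivory (with variance
    explained, ELPD-based predictive model comparison and Moran's I
    residual diagnostics), and a synthetic-woodland generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    glmmTMB,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
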