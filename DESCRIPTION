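Package: rangecast
Title: Ensemble Niche Modeling, Range-Change Accounting and Timber Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for ensemble ecological
    niche modeling (species distribution modeling) of tree species under
    past and future climate scenarios. Occurrence records are cleaned and
    rasterized to presence cells; candidate predictors are pruned by
    Spearman rank correlation; five algorithms (BIOCLIM, Domain, GLM, SVM,
    Random Forest) are fit over replicated 70/30 presence-cell splits with
    1:1 pseudoabsence sampling; replicates are evaluated by rank AUC and
    the true skill statistic (TSS) with sensitivity-specificity threshold
    selection, filtered, range-normalized and combined into a squared-TSS
    weighted consensus map; consensus maps are binarized at the lowest
    presence threshold, compared across periods into gain/loss/stable
    rasters with curvature-corrected cell areas, summarized as percent
    range change, mapped for across-GCM and across-algorithm uncertainty,
    and converted to timber value. A virtual-species simulator with known
    Gaussian niches makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
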