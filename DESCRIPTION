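Package: conntrait
Title: Structural Connectome Trait Discovery via Robust Independent
    Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts robust independent connectivity traits (SC-traits)
    from cohorts of structural connectomes by PCA denoising followed by
    repeated FastICA decompositions and a consensus over runs, tests the
    association of trait weights with group membership under
    Benjamini-Hochberg false-discovery-rate control, fits balanced
    multiple linear regressions with a sampling-without-replacement
    scheme that equates nuisance covariates across groups, and localizes
    significant traits to resting-state-network blocks through subtrait
    over-representation statistics. Includes a synthetic-cohort
    generator with planted latent traits, group-dependent loadings and
    configurable covariate confounding, so the full pipeline can be
    exercised and validated against known ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
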