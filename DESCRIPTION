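Package: stoichflex
Title: Environmental and Species-Identity Controls on Leaf Nutrient Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating within-species (plastic) from across-species
    variation in leaf nitrogen, phosphorus, and N:P ratio along environmental
    gradients. Provides quality and occurrence filters for species-by-site
    trait tables, random-forest recursive feature elimination under five-fold
    cross-validation, a model-comparison harness contrasting random forests,
    linear models, and linear mixed models across full, site-aggregated, and
    within-species-only data versions, mixed-model variance partitioning
    (marginal R-squared and intraclass correlation), order-dependent ANOVA and
    shared-effect decompositions, trait gradient analysis with species-specific
    plasticity slopes and occurrence ranges, and a hierarchical synthetic-data
    generator with known ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    ranger,
    lme4,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
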