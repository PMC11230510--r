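Package: kataegion
Title: Epoch-Stratified Kataegis Detection and Characterisation in Somatic SNV Catalogs
Version: 0.1.0
Authors@R: person("SAPCS", "Analytics", email = "analytics@example.org", role = c("aut", "cre"))
Description: Detects kataegis (focal somatic hypermutation) from per-sample SNV
    catalogs stratified by evolutionary epoch, using exact piecewise-constant
    fitting of log inter-mutation distances and a burden-adjusted distance
    threshold. Provides candidate filters based on substitution-type consistency
    and read-backed phasing, enrichment tests of kataegis proximity to
    structural-variant breakends against matched random-region simulations,
    lightweight 96-channel SBS and 32-channel SV signature refitting with APOBEC
    attribution, cohort-level association statistics (exact tests, rank tests,
    FDR, stepwise AIC GLMs), and a synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse,
    glmnet,
    SummarizedExperiment
Config/testthat/edition: 3
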