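Package: exposomix
Title: Exposome-Omics-Wide Association Analysis for Multi-Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exposome-omics-wide association study (ExWAS) toolkit for
    multi-cohort child-health studies. Fits per-IQR linear models between
    every exposure and every molecular feature across six omics layers,
    adjusts genome-wide layers with residual-SVD surrogate variables,
    applies layered multiple-testing correction (per-exposure
    Benjamini-Hochberg for genome-wide layers, effective-number-of-tests
    Bonferroni for targeted panels, plus a stringent global cutoff), runs
    sensitivity analyses (model-variant effect change, per-cohort
    inverse-variance meta-analysis with I2 heterogeneity, mutually adjusted
    multi-exposure models), builds bipartite exposure-feature association
    networks with community detection, and integrates results across layers
    (cis-eQTM pairing, miRNA-target concordance, cross-matrix replication).
    Ships a seeded synthetic-cohort generator emulating the statistical
    structure such studies assume, so the whole pipeline is testable
    without access-controlled data.
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
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
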