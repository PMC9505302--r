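Package: repgvhd
Title: TCR Beta Repertoire Diversity, Clonality and GVHD Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing T-cell receptor beta-chain (TRB) repertoires
    in the context of donor lymphocyte infusion (DLI) and graft-versus-host
    disease (GVHD). Reads VDJtools- and AIRR-style clonotype tables,
    depth-normalizes samples by seeded hypergeometric downsampling, computes
    inverse Simpson diversity, clonal-space occupancy and top-N clonal
    proportion, classifies patient repertoires against a healthy-control
    reference band, quantifies paired longitudinal diversity changes, and
    compares cumulative incidence between groups under competing risks
    (Aalen-Johansen estimator, Mantel-Haenszel hazard ratios, Gray's test).
    Includes seeded synthetic-repertoire and synthetic-cohort generators so
    the full pipeline can be exercised and validated without patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    cmprsk,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
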