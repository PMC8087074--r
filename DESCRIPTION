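Package: imccr
Title: Inter-Module Coordination Coefficients for Weighted Gene
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies coordination between modules of a weighted gene
    co-expression network with the inter-module coordination coefficient
    (IMCC), which integrates direct inter-module connectivity (the sum of
    cross-module edge weights, screened by a hypergeometric test) with
    indirect connectivity through shared partner genes (a consistency
    score and a three-node path strength).  Includes calibration of the
    integration weights against functional-annotation similarity,
    module-level map construction with global rewiring statistics
    (topology summaries, score-distribution shifts, principal component
    projections, architecture distances), connector-module detection by
    betweenness, path-length/density perturbation and edge-weight
    criteria, pathological-module-pair tracing with dissociation rates,
    and a synthetic-data generator with planted coordination strengths
    for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
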