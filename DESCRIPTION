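Package: fluxprior
Title: Carbon-Source Inference from Gene Expression with
    Expression-Constrained Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate carbon sources for their compatibility
    with a gene-expression profile using a metabolic model. Baseline flux
    limits are computed as a flux-variability envelope over near-optimal
    growth on each candidate nutrient, scaled by relative gene expression
    through gene-protein-reaction rules, and candidates are ranked by
    relative biomass production. Includes replicate-noise and gene-label
    permutation robustness analyses, readers for SBML and a JSON model
    dialect, a bounded-variable simplex solver, and a deterministic
    synthetic fixture (toy network plus condition-adaptive expression
    simulator) for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
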