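Package: sfrtsim
Title: Agent-Based Simulation of Tumor-Immune Dynamics Under Spatially
    Fractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 2D on-lattice agent-based model of interacting cancer,
    effector and regulatory immune cell populations under whole-tumor
    radiotherapy and spatially fractionated GRID radiotherapy. Initial
    conditions are read from HALO-style per-cell multiplex
    immunohistochemistry tables or produced by a synthetic slide
    generator. Radiation response follows the linear-quadratic survival
    model with proliferation-state dose scaling, delayed cell death and
    dose-dependent cycle lengthening; immune recruitment is driven by
    per-mechanism cancer death and mitosis ledgers, including
    radiation-immunogenicity driven effector recruitment. Includes a
    seeded replicate experiment runner, tumor-eradication and
    death-mechanism analytics, and Latin Hypercube parameter sampling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
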