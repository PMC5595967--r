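Package: cycleprof
Title: Computational Cell-Cycle Profiling for Phenotypic Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for cell-cycle-based phenotypic drug screening: simulation
    of per-cell DNA-content cytometry data with known ground truth, histogram
    gating of DNA-content distributions into G1/S/G2-M/sub-G1 phase fractions,
    Z'-factor plate quality control, Cell Cycle Index (CCI) scoring of compound
    fingerprints against DMSO controls, viability normalisation with
    standard-deviation cytotoxicity calls, four-parameter logistic
    dose-response fitting (EC50/EC90), complete-linkage clustering of
    cell-cycle fingerprints, and Tanimoto chemical-similarity networks.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    ape,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
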