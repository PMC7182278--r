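Package: subflux
Title: Isotope-Labeling Flux Analysis in Metabolic Subnetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies absolute metabolic fluxes through any subnetwork of a
    larger metabolic network from transient isotope-labeling data, without
    modeling label propagation from the extracellular nutrient. Atom-mapped
    networks are decomposed into self-consistent minimal subsystems whose
    local label inputs are represented by fitted analytical time-functions
    (logistic or double-logistic); label propagation is simulated by a
    reduced system of ordinary differential equations over single-atom
    elementary metabolite units; fluxes and pool sizes are estimated by
    bound-constrained weighted least squares with chi-square goodness-of-fit
    testing, Monte-Carlo confidence intervals, and input-sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
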