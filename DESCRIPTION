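Package: porelysis
Title: Stochastic Lattice Simulation of Internal Fibrinolysis and Clot
    Turbidity Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates internal fibrinolysis of fibrin clots as a stochastic
    lattice model: tissue plasminogen activator (tPA) molecules seeded inside
    a three-dimensional square-lattice fibrin network diffuse, bind and unbind
    fibers, trigger single-fiber degradation, and ride fibrin degradation
    products. Provides the clot-structure scenario catalog (thin/thick fibers,
    dense/loose networks, fixed-ratio vs fixed-concentration tPA dosing),
    scan-line pore-size measurement on partially degraded networks, lysis
    summary metrics (lag times, times to 20/50/80 percent lysis, interval
    degradation rates, fold changes, tPA transit times), and extraction of
    clot formation/degradation parameters from plate-reader turbidity curves,
    including exponential-decay fits of degradation rate against fibrinogen
    concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
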