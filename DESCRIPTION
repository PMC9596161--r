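Package: drivesim
Title: Individual-Based Simulation of Homing Suppression Gene Drives in
    Continuous Space
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Individual-based simulation of CRISPR homing and X-shredder
    population-suppression gene drives in Anopheles gambiae. Implements
    allele-level drive mechanics (germline conversion, germline and embryo
    resistance, paternal Cas9 deposition, X-shredding, somatic fitness
    costs) under four population models: a discrete-generation panmictic
    model with Beverton-Holt density dependence, its continuous-space
    extension on the unit square, and a weekly-time-step mosquito
    life-cycle model with overlapping generations, sperm storage, and
    larval competition, again panmictic and spatial. Provides equilibrium
    genetic-load estimation in a fixed-size "rescue" mode, detection of
    chasing dynamics via Green's coefficient, outcome classification, and
    migration-by-growth-rate parameter sweeps, with tidy results and
    ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
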