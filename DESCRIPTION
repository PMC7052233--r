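Package: terrabed
Title: Meta-Ecosystem Simulation of Terraced Dryland Riverbeds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the coupled vegetation-water dynamics of a terraced
    dry riverbed viewed as a meta-ecosystem: a pool of plant functional
    groups arranged along a shoot-versus-root investment tradeoff competes
    for soil water and light within each terrace, while pulsed rainfall and
    surface-runoff cascades couple adjacent terraces.  Provides the trait-pool
    constructors, square-wave rainfall forcing with hillslope runoff
    amplification, a fourth-order Runge-Kutta integrator with steady-state
    detection, community summaries (total biomass, functional diversity as
    trait-axis pulse width, composition centroid), and scenario drivers for
    downstream terrace profiles, drought-recovery runs, and rainfall-regime
    sweeps at fixed mean annual precipitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    withr
Config/testthat/edition: 3
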