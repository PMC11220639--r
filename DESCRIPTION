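Package: nickbend
Title: Parallel Nick-Repair Pathway Analysis for T4 DNA Ligase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dissecting how T4 DNA
    ligase repairs nicked DNA through parallel pathways with distinct DNA
    bending angles. Provides generators for two-channel single-molecule
    FRET intensity traces, repair-and-then-cut spot-count fields, ligation
    dose-response datasets, and two-arm 3D point clouds of ligase-DNA
    complexes; smFRET trace correction, unbiased step-finding trace
    idealization, mixture-based FRET state location, and pattern I-IV
    classification with a Monte-Carlo parallel-versus-sequential test;
    linker-constrained DNA bending mechanics (rigid duplex arms hinged at
    the nick, freely jointed chain ssDNA tether) with bend-angle
    distributions and minimum-angle quantiles; and a conformer-selectivity
    ligation-efficiency model with C50 dose-response fitting and plateau
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
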