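Package: ojiptest
Title: JIP-Test Analysis of Fast Chlorophyll Fluorescence (OJIP) Transients
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fast chlorophyll a fluorescence induction
    kinetics (OJIP transients) in stress-physiology experiments. Extracts
    the O-L-K-J-I-P landmarks from log-sampled transients, computes the
    full algebraic JIP-test parameter set (quantum yields, specific energy
    fluxes per reaction centre, phenomenological fluxes per cross-section,
    and the performance indices PIabs and PItotal), builds double-normalized
    K-band, L-band and O-I band curves with treatment-minus-control
    difference bands, and quantifies oxygen-evolving-complex and
    QA-reducing-centre fractions. Companion physiology helpers cover
    spectrophotometric chlorophyll and carotenoid quantification
    (Lichtenthaler equations), water-use efficiency and percent change
    versus control. Comparative statistics include the range-based
    variability statistic V and its between-variety difference, one-way
    ANOVA with Fisher LSD compact letter displays, balanced two-way ANOVA
    star tables, relative-to-control JIP profiles, and starred Pearson
    correlation matrices. A seeded synthetic-data module simulates factorial
    drought experiments (transients plus physiology tables) so the whole
    pipeline is testable without instrument data, and a config-driven
    command-line pipeline orchestrates simulation and analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
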