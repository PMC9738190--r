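Package: histadyn
Title: Compartmental Kinetics and Trace Analysis for In Vivo Brain Histamine
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and analysing fast voltammetric recordings of
    brain histamine. Implements a compartmental kinetic model of histaminergic
    transmission (histidine uptake, synthesis, vesicular packaging, stimulated
    release under H3 autoreceptor G-protein feedback, clearance, and
    N-methyltransferase metabolism) with an H1-triggered retrograde inhibition
    of release; drug-condition presets; evoked-trace metrics (peak amplitude,
    clearance half-life, serotonin inhibition amplitude); the cohort
    statistical battery (paired tests, Grubbs exclusion, Kruskal-Wallis,
    two-way ANOVA with Tukey-Kramer post hoc, ANCOVA slope comparison);
    synthetic-data generators; and bounded least-squares parameter recovery
    returning a classed model-fit object.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    signal,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
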