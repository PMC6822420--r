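Package: adaptivent
Title: Adaptive Mechanical Ventilation Modes, Lung Simulation and
    Cross-Over Trial Emulation
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying adaptive mechanical-ventilation modes that
    select the respiratory rate and tidal volume automatically from a target
    minute ventilation: the classical selection by Otis'
    least-work-of-breathing equation (AVM) and the newer selection by
    minimization of inspiratory power under a square-wave pressure
    assumption (AVM2). Includes fixed-point solvers for both selection
    equations with a brute-force power-curve oracle, a 100-Hz
    single-compartment lung simulator for pressure-controlled ventilation
    with end-inspiratory hold maneuvers and auto-PEEP, waveform-derived
    lung-protection metrics (static driving pressure, static compliance,
    mechanical power, mean airway pressure, expiratory time constant, Bohr
    dead space, alveolar minute ventilation), a closed-loop
    minute-ventilation controller with an end-tidal CO2 target band, a
    synthetic-cohort generator calibrated to a critically-ill ICU
    population with an ARDS subgroup, and a randomized cross-over trial
    engine with paired statistics (paired t, Wilcoxon matched-pairs,
    D'Agostino-Pearson normality, Pearson correlation, noncentral-t
    sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
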