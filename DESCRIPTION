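Package: oxyloop
Title: Closed-Loop SpO2-Targeted FiO2 Titration: Controller, Virtual
    Patients and Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for automated titration of the
    inspired oxygen fraction (FiO2) against a pulse-oximetry (SpO2) target
    range in mechanically ventilated adults. Implements a step-table
    proportional-integral FiO2 controller with a 94% setpoint, dual
    severity-matched deviation-to-step profiles, a 30-second lockout, an
    immediate 100% FiO2 rescue below SpO2 85%, and a signal-quality
    fall-back; a single-compartment shunt gas-exchange virtual patient
    (alveolar gas equation, Severinghaus dissociation curve, Berggren shunt
    mass balance, alveolar wash-in and circulatory delays); a pulse-oximeter
    model with averaging, quantization, noise, dropouts and
    low-signal-quality episodes; time-in-range outcome metrics with
    suction-window and aberrant-value exclusions; and a crossover-trial
    harness with a usual-care baseline policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
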