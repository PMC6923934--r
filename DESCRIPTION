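Package: tevckit
Title: Simulation and Analysis of Two-Electrode Voltage-Clamp Recordings of
    Electrogenic Peptide Transporters
Version: 0.1.0
Authors@R:
    person("tevckit", "developers", email = "tevckit@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of electrogenic
    membrane transporters expressed in Xenopus laevis oocytes. Provides a
    two-state charge-movement and transport-current simulator of
    two-electrode voltage-clamp (TEVC) recordings, isolation of
    pre-steady-state transient currents by double-exponential fitting,
    Boltzmann analysis of charge/voltage relationships, reconstruction of
    unidirectional rate constants from the Q/V and tau/V relations,
    voltage-resolved Michaelis-type dose-response fitting (K0.5, Imax,
    transport efficiency), and a comparative-CT (2^-deltaCT) qPCR pipeline
    including primer-efficiency estimation from dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
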