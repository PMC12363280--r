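Package: relkin
Title: Release Kinetics of Solutes from Hydrogel Depots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and parameter estimation for controlled
    release of a solute (e.g. the chemokine CXCL12) from cylindrical
    alginate-based hydrogels. Solves one-dimensional Fickian diffusion
    with a sealed base and an interaction-limited (Robin) release
    surface by Crank-Nicolson finite differences, provides the analytic
    eigenfunction-series solution as an independent oracle, fits the
    Korsmeyer-Peppas power law and classifies the release mechanism,
    estimates the effective diffusivity and surface mass-transfer
    coefficient by a real-coded genetic algorithm with simplex polish,
    reduces perfusion-bioreactor fraction-collector data (pump
    calibration, dead-volume delay, compartment mass balance), and
    generates synthetic static and perfusion datasets so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
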