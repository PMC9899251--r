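Package: flashcal
Title: Absolute Dosimetry Analysis for Ultra-High Dose Rate Proton Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for graphite-calorimeter primary-standard
    dosimetry of ultra-high dose rate (FLASH) proton pencil-beam-scanning
    fields, and the companion ionisation-chamber dose determination. Turns
    sampled core-temperature traces into absorbed dose-to-water via
    quadratic drift-curve extrapolation, the graphite specific-heat model
    and a multiplicative correction-factor chain; implements the
    reference-chamber chain (air-density, polarity, electrometer and
    calibration coefficients) with Jaffe-plot beam classification and
    two-voltage and three-voltage ion-recombination estimators for
    continuous beams; combines GUM Type A / Type B relative uncertainty
    components in quadrature, including triangular-distribution standard
    uncertainties; and generates synthetic calorimeter traces and chamber
    saturation curves with known ground truth so every stage is testable
    without beam time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
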