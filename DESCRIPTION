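Package: ureadose
Title: Urea Kinetic Dosing and Treatment-Frequency Prescription for Home Haemodialysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-pool variable-volume urea kinetic simulation of weekly
    haemodialysis cycles at periodic steady state, with the standard dose
    metrics (spKt/V, eKt/V, stdKt/V) and formula-based clinical estimators.
    Derives, by simulation-grid regression, the linear coefficients linking
    weekly standard Kt/V to residual kidney urea clearance and per-session
    equilibrated Kt/V for each treatment schedule, and uses them in a
    prescription engine that returns the minimum treatment frequency and
    required per-session dose to meet a weekly standard Kt/V target.
    Includes a seeded synthetic session-cohort generator and Bland-Altman /
    regression agreement statistics for validating the simplified formula
    against the full kinetic simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
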