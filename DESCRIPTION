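Package: rodentcam
Title: Camera-Trap Monitoring of Invasive Rodents: Events, Occupancy,
    Habitat Covariates and Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for motion-triggered camera-trap surveys of
    invasive rodents. Converts trigger-level records into 15-minute presence
    events, activity indices and nightly detection histories; fits
    single-season occupancy models with constant or night-varying detection
    and derives cumulative detection curves and the number of survey nights
    needed for confident absence; computes site-level habitat covariates
    (point-centre-quarter burrow density, structure-pole complexity,
    floristic cover); and fits negative-binomial generalised linear models
    for activity counts over a-priori candidate sets with AICc selection,
    Akaike weights and model averaging. Includes a synthetic-study generator
    with a truth record for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
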