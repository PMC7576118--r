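Package: ctds
Title: Camera-Trap Distance Sampling for Unmarked Animal Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Point-transect distance sampling for camera-trap surveys of
    unmarked animals. Fits detection functions (uniform, half-normal and
    hazard-rate keys with cosine, simple-polynomial and Hermite-polynomial
    series adjustments) to radial photo distances, converts camera operating
    time into snapshot-based survey effort restricted to diel availability
    windows computed from solar position, and combines encounter rates with
    estimated detection probability to produce density and abundance
    estimates with encounter-rate/detection variance decomposition,
    log-normal confidence intervals, AIC model selection and model
    averaging. Includes a survey-design planner (coefficient of variation
    versus number of camera sites) and a clustered-population survey
    simulator with known ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
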