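Package: perigrow
Title: Catchment-Scale Nutrient Enrichment and Periphyton Growth Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying river catchments by nutrient
    limitation and periphyton (attached algae) growth risk from routine
    water-quality monitoring data. Harmonises site-level total and dissolved
    nitrogen and phosphorus records (unit checks, half-detection-limit
    substitution for left-censored values, analytical-method screening),
    separates daily discharge into baseflow and stormflow with a Lyne-Hollick
    recursive digital filter, applies baseflow, date-window and growing-season
    filters before computing site and catchment median concentrations, fits
    log-space best-subsets linear models selected by Mallows Cp with Duan
    smearing retransformation, classifies catchments into four types from the
    Redfield mass ratio (7:1) and literature TN/TP thresholds, and rolls
    areas, populations and land use up to continent and world totals. A
    synthetic-data generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
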