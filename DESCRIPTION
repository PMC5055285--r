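Package: musselskill
Title: Physiology-Based Skill Assessment of Intertidal Body-Temperature Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts body temperatures of intertidal mussels from
    environmental forcing with models of increasing complexity (an
    air-temperature proxy, solar-elevation regressions, and a steady-state
    biophysical heat budget), pairs predicted and observed daily maximum
    temperatures during aerial exposure at low tide, and scores each model
    with categorical forecast-verification statistics (per-category hit
    rate and false-alarm ratio, and the multicategory Heidke, Peirce and
    Gerrity skill scores) over a seven-category thermal-performance
    scheme, alongside bias, mean absolute error and root mean squared
    error and an inter-logger skill baseline.  Ships a seeded generator
    of synthetic environmental forcing and multi-logger biomimetic
    temperature records so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
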