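Package: normrisk
Title: Radiological Hazard Indices, Soil-to-Plant Transfer and Monte Carlo
    Cancer Risk for NORM Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for radiological risk assessment of naturally occurring
    radioactive material (NORM) surveys built around gamma-spectrometric
    activity concentrations of K-40, U-238 and Th-232 in soil, water and
    food crops.  Covers energy calibration and reduction of NaI(Tl)
    spectra to activity concentrations, UNSCEAR-style hazard indices
    (absorbed dose rate in air, annual effective dose from external
    exposure and ingestion, representative level index, excess lifetime
    cancer risk), soil-to-plant transfer factors with IAEA cereal
    reference comparisons, descriptive site statistics, a seedable Monte
    Carlo engine for probabilistic cancer-risk estimation, and a
    synthetic-data generator (site activity profiles and NaI(Tl) spectra)
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
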