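Package: aqoi
Title: Multi-Pollutant Surface Objective Analysis and Air Quality Health
    Index Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Optimal-interpolation fusion of surface air-quality station
    observations with gridded model forecast fields.  Provides the full
    analysis chain for hourly pollutant fields (O3, NO2, PM2.5, PM10):
    innovation-based error-statistics estimation by the
    Hollingsworth-Lonnberg variogram method and a representativeness-error
    model, three-stage observation quality control, regional forecast bias
    correction with exponential decay outside regions, the optimal
    interpolation update itself, internal and cross (holdout) validation
    with significance testing, derived Air Quality Health Index (AQHI)
    mapping and exceedance climatology, and a synthetic-scene generator
    with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
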