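Package: herdcast
Title: Early Forecasting of Beef-Cattle Meat Productivity from Birth-Time
    Marker Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting post-slaughter meat productivity of
    beef cattle from traits measurable at or around birth: dam live
    weight, calf live weight at birth and calf height at the withers at
    birth.  Implements the staged prognosis workflow used in zootechnical
    practice: descriptive biometry (mean, error of the mean, standard
    deviation), reliability-tested Pearson correlations across ages and
    between body measurements, marker screening, regression-based
    forecast tables (b = r * sigma_y / sigma_x), multi-marker combined
    forecasts by arithmetic averaging, farm-level forecast-accuracy
    evaluation against realized slaughter records, and selection-effect
    propagation from live weight to slaughter indices via the breeder's
    equation.  Includes a synthetic-herd generator with configurable
    means, dispersions and correlation structure so the whole pipeline
    can be exercised and tested without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
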