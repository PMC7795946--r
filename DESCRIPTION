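Package: radonwatch
Title: Fuzzy-Rule and Regression-Tree Decision Support for Indoor Radon Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decision-support toolkit for indoor radon (Rn-222) monitoring
    with environmental sensors. Two concurrent weighted-rule Mamdani fuzzy
    inference systems score how favourable current atmospheric conditions
    are to a radon rise (correction factor, scale 0-10) and the exposure
    hazard of the measured concentration (radon risk, scale 0-100). Rule
    weights adapt to the monitored site via sigmoid-transformed Pearson
    correlations between each weather variable and radon concentration.
    Six CART regression trees trained on the accumulated knowledge base
    grade corrective and checking recommendations on a 0-5 scale, rendered
    as a spider-web report. Includes a seeded synthetic-data generator with
    diurnal and seasonal radon cycles, a delimited-text knowledge-base
    store, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
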