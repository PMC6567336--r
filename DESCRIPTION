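Package: seapenbio
Title: Non-Invasive Biometry and Biomass Estimation for Sea Pen Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biometric models and population statistics for sea pen
    (Pennatula rubra) colonies, supporting non-invasive assessment of
    size structure and biomass from ROV imagery. Provides leaf-count
    based linear size models and cubic weight models with a root mean
    square relative error metric, bias-corrected moment statistics
    (standard deviation, skewness, non-excess kurtosis), a seeded
    synthetic colony population generator with trawl-selectivity and
    ROV counting-error simulation, and an end-to-end pipeline that
    predicts per-colony weights from visible polyp-leaf counts,
    aggregates them to population biomass, and validates the prediction
    against a physically measured trawl sample.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
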