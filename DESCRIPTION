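Package: roavcurves
Title: ROAV Flavor Scoring and Surrogate Trajectory Models for Maillard
    Reaction Volatiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening aroma-active volatiles of Maillard reaction
    products and modelling their evolution over hydrolysis time. Computes the
    degree of hydrolysis from formol-titration quantities, scores GC-O-MS
    volatile tables by relative odor activity value (ROAV), classifies and
    selects key flavor compounds, queries flavor-dilution (AEDA) matrices, and
    compares three surrogate trajectory models - natural cubic spline
    interpolation, least-squares polynomial fitting, and a densify-then-smooth
    curve prediction model - by hold-out absolute prediction error. Ships the
    study tables as plain-text fixtures and a seeded synthetic-data generator
    for benchmarking the models on data with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
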