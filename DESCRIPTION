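Package: alcomort
Title: Aggregate Time-Series Analysis of Population Drinking and Cancer Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregate-level (ecological) time-series analysis of
    per-capita alcohol consumption and cause-specific cancer mortality.
    Implements lag identification by pre-whitened cross-correlation,
    construction of lag-weighted exposure series, differenced semi-log
    regression with ARIMA error structure and exogenous covariates,
    transformation of coefficients to per-litre percentage effects, and
    aggregate alcohol-attributable-fraction computation, together with a
    synthetic-data generator that produces study-shaped annual series with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
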