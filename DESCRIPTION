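Package: plateqc
Title: Statistical Quality Control and Quantification for Plate-Based
    Screening Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control of plate-based high-throughput screening
    (HTS) assays from positive and negative control wells: Z'-factor,
    three estimators of the strictly standardized mean difference
    (method-of-moments, maximum-likelihood and a robust median/MAD
    variant), Welch's t statistic, the two-sample Kolmogorov-Smirnov
    statistic, signal-to-background, signal-to-noise and coefficients
    of variation, together with threshold-based assay classification
    and per-metric ranking of competing assays.  Also quantifies
    enzymatic readouts: luminescence time-series summaries, linear
    absorbance calibration, initial rates, specific activity and
    turnover numbers, and simulates half-plate control experiments and
    progress curves so the full pipeline can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
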