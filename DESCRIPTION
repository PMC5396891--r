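Package: camarray
Title: Camera-Trap Array Study Design Evaluation by Monte Carlo Subsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating camera-trap study designs: how the
    detection probability of wildlife species responds to the number of
    clustered cameras deployed per site (the "array size") and to the
    length of the survey season. Includes a synthetic camera-trap data
    generator with known detection structure, deduplication of trigger
    events into independent site-level detections using a 30-minute
    cross-camera rule, Monte Carlo subsampling of a yearlong dataset into
    hypothetical designs, the survey and cumulative season detectability
    estimators, bounded nonlinear fitting of the saturating season
    detectability curve with confidence intervals, and pairwise comparison
    of array sizes with familywise error control robust to non-normality
    and heteroscedasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    multcomp,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
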