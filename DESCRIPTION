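Package: oehr
Title: Optimal Equal-HR Cut-Points for U-Shaped Risk in Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finds two cut-points of a continuous predictor whose relationship
    with log relative hazard in right-censored survival data is U-shaped. The
    optimal equal-HR method pairs candidate cut-points with equal fitted log
    relative hazard (from a penalized B-spline Cox fit) and selects the pair
    whose three-group categorical Cox model minimizes AIC. Includes comparator
    discretizations (median split, quartiles, maximally selected log-rank),
    predictive-performance measures (Harrell's c-index, Gonen-Heller CPE,
    integrated Brier score, R2_PM, R2_D) with cross-validation, a Weibull
    survival-data simulator with calibrated censoring, and a Monte-Carlo study
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
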