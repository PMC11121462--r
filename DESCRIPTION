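Package: honeyaudit
Title: Regulatory Quality Auditing and Botanical Classification of Honey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audit pipeline for physicochemical honey-quality data:
    type-aware regulatory threshold screening (sugars, sucrose, 5-HMF,
    moisture, free acidity, diastase activity, insoluble matter, electrical
    conductivity), conductivity-based botanical reclassification between
    flower and honeydew honey, two-tier adulteration grading
    (adulterated / suspect / compliant), descriptive statistics with
    confidence intervals and compact-letter multiple comparisons, Pearson
    correlation reporting, a Gaussian-copula synthetic data generator
    calibrated to published per-type marginals, and a multilayer-perceptron
    honey-type classifier trained by BFGS on cross-entropy loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
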