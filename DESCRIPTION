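Package: headctrisk
Title: Thyroid Dose and Lifetime Attributable Risk from Adult Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating the radiation burden of routine
    non-contrast adult head computed tomography on the thyroid gland. Generates
    seeded synthetic three-scanner cohorts, computes scan dose indices (CTDIvol,
    DLP) from tube parameters, models the out-of-field thyroid organ dose with a
    one-dimensional plateau/exponential-scatter profile on sex-specific phantom
    geometry, converts organ doses to ICRP-103 effective dose, projects the
    BEIR VII lifetime attributable risk of thyroid-cancer incidence (both an
    interpolated coefficient-table backend and a generic lifetable/excess-
    relative-risk backend), and runs the male-versus-female statistical
    comparison (normality screening, t / Mann-Whitney tests, regression,
    power analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
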