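Package: persistkit
Title: Treatment Persistence and Medical Cost Analysis from Insurance Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying persistence to biologic therapies and the
    associated medical costs from health-insurance claims data. Builds
    analysis cohorts from four-table claims bundles (enrollment, diagnoses,
    drug claims, costs), constructs refill-gap treatment episodes with
    switch detection, estimates persistence by the Kaplan-Meier
    product-limit method with Greenwood confidence bands, compares groups
    with log-rank and Gehan-Breslow Wilcoxon tests, and summarises
    12-month pre/post-initiation medical costs by category. Ships a seeded
    synthetic claims generator shaped like a Japanese employer-based
    claims database so the full pipeline is testable without access to
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
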