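Package: dupcea
Title: Within-Trial and Model-Based Cost-Effectiveness Analysis for
    Dupuytren's Contracture Treatments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for the economic evaluation of
    collagenase injection versus limited fasciectomy for moderate
    Dupuytren's contracture. Implements micro-costing and Healthcare
    Resource Group costing of patient-level resource use, area-under-the-
    curve quality-adjusted life-years with explicit death handling,
    multiple imputation by chained equations with Rubin-rules pooling,
    seemingly-unrelated-regression estimation of incremental costs and
    QALYs with a nested nonparametric bootstrap, incremental
    cost-effectiveness ratios with dominance labelling, net health
    benefit, cost-effectiveness acceptability curves and a vial-price
    threshold analysis, plus a lifetime nine-state Markov cohort model
    with age- and sex-specific background mortality and Monte-Carlo
    probabilistic sensitivity analysis. A seed-reproducible synthetic
    trial generator emulating the statistical structure of a two-arm
    hand-surgery trial makes every stage runnable and testable without
    access to confidential trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
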