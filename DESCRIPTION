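Package: voctree
Title: Decision-Tree Cost-Effectiveness Analysis of Vaso-Occlusive Crisis
    Prevention in Sickle Cell Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic modelling toolkit for comparing treatments that
    prevent sickle-cell-disease vaso-occlusive pain crises. Provides a generic
    decision-tree engine (validation, pathway enumeration, expected-value
    rollback), incremental cost-effectiveness analysis (ICER, dominance,
    extended dominance, net monetary benefit), triangular and
    percentile-anchored ("Trigen") uncertainty distributions, one-way and
    probabilistic sensitivity analysis with acceptability curves and tornado
    regression, and a concrete three-arm parameterization comparing
    crizanlizumab (5 mg/kg and 2.5 mg/kg) against l-glutamine from a Qatari
    healthcare-payer perspective, together with a synthetic model generator
    for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
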