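Package: pm25cobenefit
Title: Health Co-Benefit Assessment of PM2.5 Scenarios with the GEMM
    Exposure-Response Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates mortality attributable to long-term ambient PM2.5
    exposure on gridded concentration and age-structured population fields
    using the Global Exposure Mortality Model (GEMM) concentration-response
    function, propagates parameter uncertainty into ~95% confidence
    intervals, differences paired climate-policy scenarios to obtain avoided
    deaths, and monetizes them with value-of-statistical-life (VSL) models
    for cost-benefit accounting. Includes a synthetic-data generator that
    emulates chemical-transport-model concentration fields, clustered
    population grids with scenario age structures, and cause-specific
    baseline incidence tables, so the full pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
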