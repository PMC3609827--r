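Package: dietlp
Title: Nutrient-Constrained Diet Optimization with Cost, Greenhouse Gas
    and Uncertainty Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear-programming optimization of daily diets over a food
    database: minimize daily cost or greenhouse-gas emissions subject to
    nutrient requirement bounds, food-specific quantity limits, category
    aggregates, linked-ingredient ratios and budget caps. Ships sixteen
    built-in dietary scenarios, a deterministic two-phase simplex solver
    with a semicontinuous minimum-portion rule, a Monte Carlo engine that
    propagates uncertainty in prices (gamma), nutrient contents (normal),
    food wastage (beta) and requirements (normal) into 95 percent
    simulation intervals, a synthetic food-database generator for fully
    reproducible analyses, and reporting of scenario comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
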