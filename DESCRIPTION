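Package: pollenclim
Title: Pollen-Based Reconstruction of Holocene Seasonal Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative reconstruction of Holocene seasonal
    temperatures (mean annual, warmest-month and coldest-month) from fossil
    pollen records. Implements plant-functional-type (PFT) affinity scoring
    of pollen assemblages, the modern analogue technique with squared chord
    distance and analogue thresholds, weighted-averaging partial least
    squares as a cross-check transfer function, leave-one-out and h-block
    cross-validation with a data-driven h selection rule, random-transfer-
    function significance testing, radiocarbon recalibration and age-depth
    screening, glacio-isostatic temperature correction via local lapse
    rates, Monte-Carlo anomaly stacking onto a 2-degree grid with 95%
    uncertainty bands, redundancy analysis with variance partitioning, and
    empirical orthogonal function analysis of the gridded anomalies. A
    seeded synthetic-data generator with Gaussian-niche taxa and known
    temperature truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
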