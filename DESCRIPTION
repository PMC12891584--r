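Package: alanphen
Title: Autumn Senescence Phenology Models with Artificial-Light-at-Night Forcing
Version: 0.1.0
Authors@R: person("Maintainer", "alanphen", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Process-based models of the autumn date of foliar senescence (DFS)
    driven by cooling degree days and photoperiod (CDD, DM, SIAM, DMT families),
    extended with an exponential artificial-light-at-night (ALAN) forcing
    coefficient. Includes particle swarm calibration, model comparison by
    correlation, RMSE and AIC, preseason-optimized partial-correlation and
    ridge-regression sensitivity analysis, Theil-Sen/Mann-Kendall trends,
    moving-window modulation of climate sensitivity by ALAN, ALAN-GDP projection
    regression, and a seeded synthetic-data generator so the full pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
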