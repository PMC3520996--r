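Package: abaclim
Title: Projecting Abalone Distribution and Abundance Under Ocean Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for projecting the
    future distribution and abundance of harvested abalone (blacklip and greenlip)
    under contrasting greenhouse-gas emissions scenarios. Implements skill ranking
    and multi-model averaging of global climate model (GCM) sea-surface-temperature
    anomalies, change-factor statistical downscaling onto a fine baseline
    climatology built with thin-plate-spline smoothing under generalized
    cross-validation, ensemble (negative-binomial GLM plus boosted regression tree)
    abundance models projected at decadal time slices, fishing-ground delineation
    and change mapping against a minimum-density threshold, a late-summer
    thermal-tolerance overlay, and the statistics of a juvenile-mortality
    temperature experiment. A synthetic-data module generates every input with a
    known ground truth so each stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
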