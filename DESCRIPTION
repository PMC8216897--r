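Package: ehacube
Title: Emerging Hotspot Analysis of Annual Forest-Loss Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Space-time pattern mining for annual first-loss rasters such as
    the Global Forest Change loss-year product. Builds a space-time cube of
    yearly loss counts, computes per-bin Getis-Ord Gi* z-scores with a
    space-time neighborhood, tests per-location trends with the
    Mann-Kendall statistic, and classifies each location into one of the
    eight emerging-hotspot categories (new, consecutive, intensifying,
    persistent, diminishing, sporadic, oscillating, historical). Includes a
    protected-area overlay, driver attribution via covariate summaries,
    Kruskal-Wallis tests and interpretable classification trees, and a
    synthetic-scenario generator with planted space-time hotspot patterns
    and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
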