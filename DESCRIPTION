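Package: phenospring
Title: Spring Phenology Onset Models for the Beginning of the Growing Season
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements, calibrates, and compares four temperature-driven
    spring phenology models that predict the beginning of the growing season
    (BGS) from daily air temperature and precipitation: a growing degree-day
    model (GDD), the Biome-BGC onset rules for woody plants and grasses
    (BBGC), a number-of-growing-days model (NGD), and a two-phase
    chilling-forcing model (NCD-GDD). Includes a synthetic daily climate and
    onset-observation generator emulating gridded reanalysis and satellite
    phenology products, climate-based subdivision of wide-latitude biomes
    into cool and warm classes, per-biome parameter estimation by error
    sum-of-squares minimization over a random half split of pixels, and the
    standard evaluation metrics (R-squared, RMSE, mean absolute error,
    interannual Pearson correlation, cumulative frequency of absolute
    differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
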