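Package: arcbioclim
Title: Bioclimatic Indicators and Extreme-Event Change Analysis for Arctic Gridded Climate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bioclimatic analysis of daily gridded weather over
    high-latitude land: a synthetic ERA5-Land-like daily weather generator
    with controllable warming trends and event injection; eleven annual
    bioclimatic indicators (growing degree days and season length, frost
    during the growing season, freezing degree days, snow season length,
    summer warmth index, rain-on-snow and winter warming event counts,
    heatwave and vapour-pressure-deficit magnitude indices, high wind
    events); pixel-wise Sen's slope and Mann-Kendall trend maps;
    KMeans climate classification from normalized climatologies;
    latitude-aware surface-area accounting of event coverage and its
    trends; detection of newly emerging and disappearing extreme-event
    regimes between 30-year windows; and a bivariate synthesis of
    significant change in seasonal versus event-related variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
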