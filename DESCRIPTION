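Package: manchot
Title: Movement, Diving and Habitat Analysis for Juvenile King Penguin
    Biologging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for satellite-relay biologging data
    from juvenile and non-breeding king penguins dispersing from the Crozet
    Archipelago. Provides speed filtering of Argos location series
    (McConnell-style root-mean-square filter), net squared displacement (NSD)
    segmentation into encamped and transiting latent states with a Gaussian
    hidden Markov model, hierarchical clustering of hourly dive records into
    traveling and foraging behavioural modes (Manhattan distance, UPGMA),
    penalized-spline binomial habitat models with individual random effects
    and exhaustive AIC model selection, and orientation analysis of 12-h
    movement segments relative to wind and ocean-current directions. A
    synthetic study-data generator (correlated random walk tracks, duty-cycled
    dive records, smooth gridded environmental fields) makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lubridate,
    mgcv,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
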