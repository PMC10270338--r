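Package: mpnoise
Title: Noise Robustness of the Time-Series Matrix Profile
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify how robust matrix-profile computation is to
    additive noise in a univariate time series. Provides an exact STOMP-style
    matrix profile with motif and discord location, two parameterised noise
    injectors (duplicated anomalies and irrelevant uniform features), an exact
    and FastDTW alignment between profiles of different lengths with a
    normalised dissimilarity score, seeded synthetic generators emulating
    keystroke-timing, calf-accelerometer and city-traffic series, and a study
    pipeline that sweeps the standard ten noise conditions and emits tidy,
    reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
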