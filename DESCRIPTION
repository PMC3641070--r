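Package: emddfa
Title: Empirical Mode Decomposition Embedded Detrended Fluctuation Analysis for Postural Sway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short- and long-term fractal scaling of center-of-pressure
    (COP) magnitude series with a detrended fluctuation analysis whose detrending
    and time scales are derived from empirical mode decomposition of the signal
    itself (EMD-DFA). Includes conventional detrended fluctuation analysis and
    classical posturographic summary metrics (sway speed, 95% confidence-ellipse
    area) for comparison, seeded generators of fractional Gaussian noise,
    two-regime composite signals and COP-like trajectories for validation, readers
    for delimited force-plate exports, and a command-line interface.
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
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
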