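Package: ndsynergy
Title: Normalized Diagonal Sampling Screens for High-Order Antibiotic Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulate, quantify and score high-order antibiotic
    combination screens built around the Minimax Effective Concentration
    Index (MECI). Provides normalized diagonal sampling (NDS) design
    generation with plate-layout randomization, growth-curve quantification
    from OD600 time series (area under the growth curve and maximum growth
    rate), MECI / Total and Emergent Synergy Score / diagonal FICI-bound
    scoring with interpretive classification, a pooled-Hill dose-response
    simulator producing realistic plate-reader datasets, and a brute-force
    full-factorial oracle that empirically verifies that diagonal sampling
    recovers the MECI whenever growth responses are non-paradoxical.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
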