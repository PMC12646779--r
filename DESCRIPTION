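Package: partmig
Title: Classifying Partial-Migration Strategies from GPS Telemetry and
    Explaining Them from Resource Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to classify individual ungulate movement strategies
    (resident, dual-range migrant, multi-range migrant) from GPS
    relocation data, using Brownian bridge movement model or kernel
    occurrence distributions, isopleth-restricted Bhattacharyya affinity
    overlap metrics and k-means clustering, and to relate the resulting
    strategies to spatial and year-to-year variation in resources via
    beta-regression model selection with AICc. Includes an
    Ornstein-Uhlenbeck trajectory simulator and a Gaussian random field
    landscape generator so every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
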