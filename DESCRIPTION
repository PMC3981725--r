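Package: fticrdom
Title: FT-ICR-MS Dissolved Organic Matter Processing and Mesocosm Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of ultra-high-resolution
    (FT-ICR) mass-spectral peak lists from dissolved organic matter (DOM)
    decomposition experiments. Provides internal mass recalibration against a
    calibrant database, exhaustive CHNOSP molecular-formula assignment under
    element-ratio rules, cross-sample mass alignment with replicate-based
    noise filtering, multivariate DOM and microbial-community statistics
    (Bray-Curtis, NMDS, ANOSIM, covariance PCA, evenness, paired differential
    tests with a randomization null), bacterial production, respiration and
    growth efficiency budgets, a two-endmember terrigenous-DOM mixing model,
    and a seeded synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
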