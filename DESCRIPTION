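Package: metsage
Title: Metabolic Syndrome, Brain Morphology and Brain-Age Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking metabolic syndrome (MetS) to brain
    morphology and brain aging: NCEP-ATP III/IDF component flags and an
    integer severity score, mass-univariate unique-effect association scans
    of cortical surface area, thickness and subcortical volumes against
    single MetS components or the severity score (two-step residualisation,
    Benjamini-Hochberg FDR or maxT permutation correction), per-feature AIC
    winning-model selection, partial least squares brain-age prediction
    with cross-validated age-bias-corrected brain-age gaps, distributional
    group comparisons of gaps (Kolmogorov-Smirnov tests, propensity-score
    matched t-tests), and a synthetic-data generator with planted ground
    truth so every stage is testable without access-restricted cohort data.
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
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
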