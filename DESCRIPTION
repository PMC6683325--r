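Package: gutmaturity
Title: Gut Microbiota Maturity Scoring, Plasma Proteome Response Mapping,
    and Diet-Ingredient Association Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gut microbial community development in
    early childhood and its response to nutritional intervention. Fits a
    sparse random-forest "microbiota age" regression on a healthy reference
    birth cohort and scores test samples as microbiota-for-age z-scores
    (MAZ), working identically on taxonomic and functional pathway-module
    abundance tables. Implements empirical-Bayes moderated differential
    abundance for plasma proteome panels, healthy-growth-/SAM-discriminatory
    protein set construction, arm-normalized treatment-effect maps,
    anthropometry correlate sets, and a rank-correlation screen for
    complementary-food-ingredient effects on bacterial strains. Ships a
    synthetic cohort generator with known ground truth for end-to-end
    parameter-recovery testing.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    biomformat,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
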