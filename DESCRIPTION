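Package: milresidence
Title: Mother-in-Law Co-Residence from Household Rosters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers mother-in-law/daughter-in-law co-residence from the
    "relationship to household head" codes recorded in household-survey
    rosters (DHS-style Person Recode files). Builds all within-household
    member dyads, resolves each pair's kin relation through a head-anchored
    relationship matrix, flags currently married women 15-49 who share a
    household with their husband's mother, estimates survey-weighted
    co-residence proportions by five-year age group, and decomposes change
    between two surveys into age-composition and rate-schedule components
    (Kitagawa two-factor decomposition). Includes a synthetic household
    generator with known ground truth for validation, and a command-line
    pipeline for simulate/estimate/compare/decompose runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
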