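Package: sbtoxecon
Title: Health-Economic Markov Modelling of Radiation-Induced Small Bowel Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort state-transition (Markov) model with embedded decision
    trees ("Markov cycle trees") for late small-bowel toxicity after pelvic
    radiotherapy in rectal-cancer survivors. Compares 3D-CRT, IMRT and
    IMRT/IGRT through normal-tissue-complication-probability (NTCP) scaling
    of half-yearly toxicity transition probabilities, values lifetime direct
    and productivity costs and quality-adjusted life years with discounting,
    and provides one-way deterministic (tornado) and probabilistic (Monte
    Carlo) sensitivity analyses, age-cohort hospitalization scenarios and
    synthetic life-table, incidence and utility fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
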