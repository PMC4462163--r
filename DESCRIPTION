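Package: wholegrainr
Title: Whole Grain Intake Estimation from Food Diary Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole grain intake from multi-day food diary records
    and a whole-grain food composition registry. Converts eating occasions to
    grams of whole grain on a dry-matter ingredient basis (with cooking-loss
    correction), averages over diary days, applies food-level whole-grain
    content cut-offs (any / >=10 % / >=51 %), adjusts for energy intake
    (g per 10 MJ per day), classifies intake into 16 g servings, attributes
    intake to food commodity groups and grain types, and summarises groups
    with survey-weighted medians and interquartile ranges. Group comparisons
    use hand-implemented Mann-Whitney (exact by enumeration at small n),
    Kruskal-Wallis with tie correction, and a weighted linear trend test.
    Includes a zero-inflated synthetic diary-survey generator with calibration
    so the full pipeline is testable without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
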