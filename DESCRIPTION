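Package: ffqtools
Title: Scoring and Method-Comparison Toolkit for Online Food Frequency Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, validates, and scores semi-quantitative food frequency
    questionnaires (FFQs) of the EPIC-Norfolk family. Derives per-item portion-size
    series and nutrient composition from consumption-survey records, converts
    questionnaire responses into daily nutrient, percent-energy, and food-group
    intakes, screens for implausible energy reporting against a Henry-equation
    basal metabolic rate floor, and runs the standard two-instrument agreement
    battery: Bland-Altman limits of agreement, quartile cross-classification,
    correlations, energy-adjusted linear-model comparisons, and food-group t
    tests. A seeded synthetic-cohort generator with known measurement-error
    ground truth makes the full pipeline testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
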