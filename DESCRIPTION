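Package: hcstTier
Title: Nutrient Profiling of 24-Hour Dietary Recalls with the Health
    Canada Surveillance Tool Tier System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the 2014 Health Canada Surveillance Tool (HCST)
    Tier nutrient-profiling system as a reusable analysis pipeline for
    24-hour dietary recall surveys. Foods are classified into Tiers 1-4
    (or one of nine non-tier "other food" categories) from sodium, total
    fat, saturated fat, and sugar thresholds per reference amount;
    recalls are aggregated into per-respondent servings, energy by tier,
    percent energy from foods-to-limit, and nutrient densities. Includes
    Institute of Medicine estimated-energy-requirement equations for
    energy-misreporting classification, survey-weighted estimation with
    bootstrap balanced repeated replication (500 replicate weights),
    weighted compliance-quartile analysis with covariate-adjusted group
    means, and a seeded synthetic-data generator with known ground truth
    emulating the structure of a national nutrition survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
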