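Package: recall24
Title: Processing and Analytics for Tablet-Based 24-Hour Dietary Recall Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Back-end processing for two-table 24-hour dietary recall exports
    as collected by tablet-based interview tools in East African field studies.
    Resolves food codes against primary and secondary food-composition tables
    with sentinel codes for unknown meals and new recipes, computes recipe
    nutrients per 100 g, converts utensil-based portion reports to grams,
    derives per-meal and per-person-day intakes of eleven nutrients, applies
    interview quality-control rules (breastfeeding consistency, time gaps,
    implausible portions), renders field reports and dietary profiles, and
    provides meal-structure, chrono-nutrition and food-away-from-home
    analytics. Includes a seeded synthetic-cohort generator emulating the
    two-table export for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
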