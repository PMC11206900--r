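Package: dietscale
Title: Scaling Cohort Nutrient-Density Profiles to Athlete Energy Requirements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the nutritional adequacy of diets scaled to athlete energy
    requirements. A cohort nutrient-density profile (nutrient amounts per
    reference energy, e.g. per 2000 kcal) is scaled proportionally to the daily
    energy requirement of each athlete, estimated from lean body mass via the
    Cunningham resting-metabolic-rate equation or supplied directly. Derived
    quantities include absolute and relative protein provision, daily and
    per-meal leucine, and energy-indexed fiber targets. Scaled diets are
    screened against Dietary Reference Intake targets (RDA, AI, DGA, CDRR) and
    tolerable upper intake levels with direction-aware semantics and
    UL-applicability caveats. Bundled fixtures cover a completely plant-based
    cohort profile and a professional American-football position roster, and a
    synthetic-data generator produces rosters and density profiles with
    configurable statistical structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    yaml,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
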