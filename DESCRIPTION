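Package: kleptoCarbon
Title: Carbon Budgets for Kleptoplastidic Mixotrophic Ciliates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for assembling the carbon budget of a
    kleptoplastidic (chloroplast-stealing) mixotrophic ciliate from
    batch-culture observations: exponential growth and mortality rates,
    Frost clearance and ingestion rates with the Heinbokel grazer-averaging
    modification, single-cell 14C inorganic carbon uptake from light/dark
    scintillation pairs, biovolume-to-carbon conversion, gross growth
    efficiency, and the partitioning of acquired carbon between ingestion
    and photosynthesis. Includes a mechanistic predator-prey simulator of
    starvation and prey-acclimation experimental designs with realistic
    measurement noise, so that every estimator can be verified by parameter
    recovery against a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
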