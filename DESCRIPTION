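Package: reefseed
Title: First-Order Assessment of Coral Population Self-Seeding from Reef Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether broadcast-spawning coral populations
    (Pocillopora spp.) on a reef shore can produce enough larvae to support
    their own recovery. The pipeline estimates percent cover from photoquadrat
    point counts and grid scores, converts settlement-tile and quadrat
    densities into shore-wide abundances per life stage and habitat, estimates
    egg and zygote production from an allometric diameter-to-tissue-area
    calibration with pooled literature fecundity and fertilization rates,
    propagates fecundity and fertilization uncertainty by Monte Carlo
    sampling, and combines production with observed recruitment into a
    self-seeding sufficiency report. A seeded synthetic-survey generator
    produces census tables with known ground truth so that every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
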