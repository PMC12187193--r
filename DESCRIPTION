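Package: respscope
Title: Individual Aerobic Performance Phenotyping from Intermittent-Flow
    Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes intermittent-flow respirometry oxygen traces of fish
    measured across a temperature gradient into per-individual standard
    metabolic rate (SMR), maximum metabolic rate (MMR) and aerobic scope,
    applies Boltzmann-Arrhenius temperature standardization and allometric
    mass correction, and classifies individuals into low, intermediate and
    high aerobic performance phenotypes with a percentile rank-scoring
    system. Includes a seeded simulator of realistic oxygen traces with known
    thermal performance curves, so the whole chain is testable by parameter
    recovery, plus cohort-level summaries, CSV/JSON input-output and a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
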