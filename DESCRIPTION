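Package: corescope
Title: Hybrid Abundance-Occupancy Core Microbiome Extraction with Core Index Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies core microbiome members in amplicon feature tables by a
    hybrid abundance-occupancy definition combined with Core Index (CI) and
    Normalized Core Index (NorCI) scoring, as used for tracking the early-life
    microbiome of sea cucumber (Apostichopus japonicus) larvae across
    developmental stages. Provides readers and validators for feature-table,
    taxonomy and sample-metadata TSV files; organelle filtering, rarefaction,
    taxonomic rank collapse and relative-abundance conversion; whole-dataset
    and stage-restricted (pioneer, juvenile, pre-/post-gut-development) core
    extraction with an enrichment screen and stage-exclusivity detection; a
    Dirichlet-multinomial synthetic community generator with planted ground
    truth for recovery benchmarking; specific-growth-rate summaries for
    feeding assays; and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
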