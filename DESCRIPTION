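Package: comutscreen
Title: Pan-Cancer Co-Mutation Screening for Panel Sequencing Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coverage-aware screening of somatic co-mutation across
    heterogeneous targeted gene panels. Builds per gene pair and per
    cancer type 2x2 contingency tables restricted to sequencing assays
    that cover both genes, tests concurrence and mutual exclusivity with
    one-tailed Fisher exact tests, and controls the false discovery rate
    with Benjamini-Hochberg adjustment. Integrates discrete copy-number
    and gene-fusion events into alteration status under Cancer Gene
    Census mutation-type gating, associates oncogenotypes with vital
    status and sample type, and screens cell-line feature matrices
    (protein arrays, gene dependencies, drug sensitivities) for
    mutation-associated differences with lineage-adjusted linear models.
    Ships seeded simulators of registry-style and cell-line data with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
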