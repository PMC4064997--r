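Package: ToxProfiler
Title: Bioassay Response Profiling for Animal Acute Toxicity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sparse compound-by-bioassay response matrices from
    high-throughput screening outcome records, ranks bioassays by their
    relevance to a binary animal acute-toxicity endpoint (balanced
    accuracy, an L relevance score and chi-square association), selects a
    top assay panel, and prioritizes compounds by a consensus S score
    computed from normalized response contributions. Includes a seeded
    planted-signal simulator of sparse screening matrices so the full
    selection and scoring workflow can be validated offline, plus a
    pipeline runner with a provenance manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Cheminformatics, Pharmacogenomics, Classification
RoxygenNote: 7.3.3
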