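Package: regulonkit
Title: Qualitative Regulatory Network Analysis for Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing and analysing qualitative gene-regulation
    data in bacteria. Provides a declarative regulation data model covering
    transcription-factor binding, attenuation, translational regulation and
    substrate-level enzyme modulation, with referential validation and
    content statistics; construction of the gene-level signed regulatory
    network with operon-aware expansion of regulatory targets; eigenvector
    (power-method) ranking of genes by regulatory influence; gene-group
    algebra with hypergeometric regulation-enrichment analysis; signed
    parity propagation that classifies upstream entities (including
    metabolic-reaction influences) as net activators or inhibitors of a
    target; elliptical and layered network layouts; XGMML export for
    Cytoscape; a seeded synthetic-model generator with a ground-truth
    ledger; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
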