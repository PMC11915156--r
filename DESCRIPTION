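Package: redoxmap
Title: Site-Level Cysteine Redoxome Profiling from Differential Alkylation Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the cysteine redoxome from differential
    alkylation (thiol-blocking/reduce/relabel) bottom-up proteomics
    experiments. Classifies each cysteine site per replicate as oxidized,
    reduced or unlabeled from variable-modification mass tags, applies a
    replicate reproducibility filter, assigns reproducible sites to the
    fifteen regions of the four-set redox Venn diagram to isolate dynamic
    and reactive cysteines, scores flanking-sequence motifs with
    pLogo-style exact binomial enrichment, summarises redox state by
    subcellular compartment, and performs label-free protein abundance
    comparisons. Ships a truth-annotated synthetic data generator so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
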