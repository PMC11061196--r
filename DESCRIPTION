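Package: soilnet
Title: Fertilizer-Driven Soil Bacterial Community Structure, Co-Occurrence
    Networks and Temporal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicated fertilizer field trials that
    profile soil bacterial communities (16S amplicon feature tables) together
    with soil chemistry and crop traits.  Implements replicate aggregation and
    standardization of feature tables, rarefaction-based alpha diversity,
    principal-component ordination with load-quantity contributor scoring,
    complete-linkage clustering of taxa into fertilizer-linked clusters,
    co-occurrence network construction with greedy complete-graph center
    extraction and Guimera-style hub cartography (within-group degree and
    participation coefficient), stage-to-stage frequency-difference dynamics,
    and the shared statistical machinery (PERMANOVA, Tukey-Kramer with compact
    letter display, variance-gated t-tests).  A synthetic field-trial
    generator provides ground-truthed studies for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
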