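Package: crestmark
Title: Toxicant Transcriptome Profiling and Biomarker Selection for Neural
    Crest Cell Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microarray studies of toxicant-exposed
    human neural crest cells. Implements paired-design differential
    expression with an empirical-Bayes moderated t-statistic, blinded
    compound classification with one-against-one linear support vector
    machines and pairwise probability coupling, gene-set
    over-representation analysis against flat pathway collections and a
    GO-like directed acyclic graph (classic and elim algorithms),
    ToxPi-style six-axis toxicity profiles, two candidate-biomarker
    selection tracks, and a separation-units quality metric for biomarker
    sets with a bootstrap null distribution. Ships a synthetic-study
    generator that reproduces the study design (six compounds, matched
    control groups, planted differential-expression signatures) so every
    stage is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
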