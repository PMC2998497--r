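Package: ppiEvoRate
Title: Determinants of Protein Evolutionary Rates in Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing what governs the evolutionary rates of
    proteins embedded in a protein-protein interaction (PPI) network.
    Computes per-protein network and annotation features (degree, local
    clustering coefficient with sparse/dense-part classification,
    coefficient of functionality with same/different-functional
    classification, protein-complex membership counts), screens
    orthologous alignments by e-value/similarity/overlap/gap thresholds,
    estimates Kimura-corrected amino-acid distances from aligned ortholog
    pairs, and runs the downstream inference chain: Spearman and partial
    rank correlations, multivariate regression, principal component
    analysis with eigenvalue-based component retention, Mann-Whitney
    group comparisons and Fisher exact tests.  A synthetic-data generator
    plants a latent evolutionary-constraint variable that jointly drives
    expression, complex membership, connectivity and sequence divergence,
    so the whole pipeline can be exercised and validated end to end
    without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
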