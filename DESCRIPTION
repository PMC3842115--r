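Package: ProteoPool
Title: Pooled-Reference Isobaric Proteome Integration, Protein-Space PCA, and
    GO Elimination Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates multi-run isobaric-tag (iTRAQ 8-plex) protein
    quantification through a common reference pool channel, filters to proteins
    quantified in every sample, and characterises the resulting proteome matrix
    by hierarchical clustering of samples and principal component analysis with
    proteins as observations. Gene Ontology enrichment is assessed by a
    hypergeometric detection test and by rank tests on principal-component
    protein scores (one-sided Wilcoxon on absolute scores, two-sided Wilcoxon,
    Kolmogorov-Smirnov) under a most-specific-first elimination over the
    ontology graph. Cell-type marker signatures are derived by intersecting
    top-k lists of signed component scores. A synthetic-data generator emulates
    the multi-run pooled-reference design, with planted group effects and
    score-enriched ontology terms, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Clustering, PrincipalComponent, GO
RoxygenNote: 7.3.3
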