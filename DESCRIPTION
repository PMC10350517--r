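Package: mixsplice
Title: Auditing Cell-Type Composition Confounds in Alternative Splicing
    Analyses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether an apparent condition-dependent shift in
    exon inclusion (PSI) measured in bulk RNA-seq of mixed cell populations
    reflects splicing regulation within cells or a change in cell-type
    composition. Provides marker-gene curation from pure reference
    transcriptomes, composition proxies (fraction-of-pure expression, sign
    counts, paired tests, non-negative least-squares weight estimation), PSI
    estimation from inclusion/skipping junction counts with a likelihood-ratio
    test of |delta PSI| > c, a delta-delta correlation diagnostic relating
    condition-wise to cell-type-wise splicing differences, an explicit
    two-cell-type mRNA mixture model with efficiency-corrected delta-delta-Ct
    qPCR arithmetic for isoform ratios, and a synthetic-data generator that
    emulates a neuron/astrocyte co-culture in which a neurotoxic stimulus
    shifts composition without changing within-cell-type splicing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
biocViews: AlternativeSplicing, RNASeq, GeneExpression, Transcriptomics,
    DifferentialSplicing, CellBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
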