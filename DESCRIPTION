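Package: dcenet
Title: Differential Coexpression Network Analysis for Two-Condition
    Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds differential (DCEN) and constitutive (CCEN) coexpression
    networks from two-condition time-course expression data via a scored,
    permutation-tested comparison of per-condition Spearman correlations;
    characterizes their tree-like topology against degree-preserving and
    data-randomization null models, including a signed-triad census; clusters
    network components by Gene Ontology semantic similarity (Schlicker
    relevance similarity with best-match-average gene similarity) and
    quantifies within/between-cluster link densities with randomization
    z-scores; and infers differentially activated transcription factors by
    degree-matched co-occurrence randomization. Includes a synthetic-data
    generator with planted coexpression structure so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'ontology.R'
    'semantics.R'
    'clustering.R'
    'coexpression.R'
    'dcenet-package.R'
    'tf.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic.R'
    'topology.R'
    'utils.R'
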