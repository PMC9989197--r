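Package: abaffinity
Title: Structure-Derived Featurization and Affinity Classification of
    Antibody-Antigen Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for classifying antibody-antigen complexes into high- and
    low-binding-affinity groups from their three-dimensional structures.
    Provides parsing of role-annotated PDB complexes, a side-chain-aware
    residue contact criterion, epitope/paratope and per-CDR interface
    definitions, four contact-counting feature sets (pairwise amino-acid
    counts, per-CDR chemical-class counts, interface multivalency, antibody
    descriptive features), residue interaction network (SIN) scores,
    amino-acid interface fitness (AIF) propensity scores, adapters for
    externally computed per-residue surface scores and per-complex
    energetics, leakage-aware dataset curation (nanobody removal,
    heavy-chain homology filtering, middle-drop-out), and a repeated
    stratified cross-validated classifier with ANOVA-F feature selection,
    label-randomization controls, feature importances and misclassification
    tracking. A synthetic complex generator with planted contact geometry
    and affinity labels supports fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    bio3d,
    Biostrings,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    randomForest,
    e1071,
    nnet,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, StructuralPrediction,
    Proteomics, Network
RoxygenNote: 7.3.3
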