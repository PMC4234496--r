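Package: egonet
Title: Ego-Network Module Discovery for Phenotype-Predictive Gene Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies ego-network modules in a molecular interaction
    network whose member genes' expression collectively predicts a binary
    phenotype. Each candidate ego with two or more interaction partners is
    grown outward by snowball sampling, scoring every level by
    cross-validated classification accuracy (SVM, KNN or random forest)
    and stopping when accuracy drops. Module significance is assessed by
    label-permutation tests, per-gene contributions by out-of-bag
    permutation importance from a random forest, and genes are ranked
    globally by the sum over modules of module score times node
    importance. Includes a mutual-information subnetwork baseline, a
    scale-free simulation harness with planted phenotype-driving modules,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    class,
    randomForest,
    ranger,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, Classification, GeneExpression, GraphAndNetwork
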