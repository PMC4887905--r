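Package: mirlsa
Title: miRNA-Disease Association Prediction in a Latent Semantic Space
Version: 1.0.0
Authors@R:
    person("Claire", "Moreau", email = "claire.moreau@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA-disease associations with a vector space
    model. Five heterogeneous feature blocks per miRNA (ontology-weighted
    disease associations, genomic-proximity neighbors, resource-allocation
    weighted targets, TF-IDF literature words, and family membership) are
    concatenated into one sparse matrix, reduced by truncated singular
    value decomposition, and queried by cosine similarity to a disease
    vector. Includes Lin semantic similarity over a MeSH-style disease
    tree, per-disease five-fold cross-validation with ROC/AUC, rank-based
    flagging of putative-false and novel associations, a synthetic bundle
    generator with planted cluster structure, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
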