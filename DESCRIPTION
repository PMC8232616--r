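Package: sublocr
Title: Sub-Organellar Protein Localisation from Sequence Encodings and
    Language-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the sub-organellar localisation of peroxisomal
    (matrix vs. membrane) and mitochondrial (outer membrane, inner
    membrane, intermembrane space, matrix) proteins from amino-acid
    sequence.  Protein sequences are converted into classical per-residue
    encodings (one-hot, ten physico-chemical factors, position-specific
    scoring matrices mapped through a sigmoid) pooled to fixed-length
    vectors, and combined with per-protein language-model embedding
    blocks consumed as delimited tables.  The best combination of
    feature blocks is chosen by step-forward selection nested inside a
    stratified double cross-validation, with hyperparameters and class
    weights tuned in the inner loop; support vector machines, random
    forests, penalised logistic regression and partial least squares
    discriminant analysis are available as classifiers.  Includes a
    synthetic-data generator emulating the study conditions so the full
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    glmnet,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
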