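Package: goanoise
Title: Predicting Noisy Gene Ontology Annotations from Evidence Codes and
    Sparse-Representation Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies likely-incorrect (noisy) Gene Ontology annotations of
    genes. Genes are embedded by their true-path-propagated annotation
    profiles; a nonnegative l1-regularised sparse representation of each
    gene's profile over the remaining genes yields a semantic similarity
    matrix, and similarity-weighted neighbourhood votes score every annotated
    term. Per-evidence-code noisy-annotation ratios, estimated from pairs of
    archived annotation releases, down-weight unstable annotations, and the
    weights are propagated to ancestor terms over the ontology graph. The
    fused score flags low-scoring annotations as noisy, with descendant
    expansion under the true path rule. Includes OBO and GAF parsers, random
    and lowest-frequency baselines, bootstrap precision/recall/F1 evaluation,
    a majority-vote function-prediction assessment, and a synthetic
    ontology/annotation generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
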