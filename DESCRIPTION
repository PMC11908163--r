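Package: structembed
Title: Structure Embeddings for Scalable Protein Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms protein chains and multimeric assemblies into
    fixed-length vectors whose cosine similarity approximates the TM-score,
    using a permutation-invariant transformer aggregator trained as a twin
    network. Includes Kabsch superposition and TM-score ground truth, a
    synthetic backbone generator (helices, strands, coils, perturbation
    families, symmetric assemblies), an exact and HNSW-based approximate
    vector index, and retrieval benchmarks (sensitivity up to the first
    false positive, tri-state fold/superfamily/family labelling, TM-score
    correlation diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
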