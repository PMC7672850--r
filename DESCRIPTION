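Package: mhsnmf
Title: Multi-View Hessian-Regularized Symmetric Nonnegative Matrix
    Factorization for Microbiome Sample Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative clustering of multi-omics sample cohorts by
    multi-view Hessian-regularized symmetric nonnegative matrix
    factorization (MHSNMF). Builds per-view sample-sample affinity
    graphs (locally scaled Gaussian or cosine kernels with kNN
    sparsification and symmetric normalization), estimates per-view
    Hessian energy operators that capture the curvature of each data
    manifold, and alternates multiplicative updates of per-view factors,
    a consensus factor and closed-form simplex view weights. Includes
    clustering evaluation (accuracy under optimal label matching,
    normalized mutual information), out-of-sample embedding and
    k-nearest-neighbour classification of new samples, seeded synthetic
    multi-view generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
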