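Package: heatlink
Title: Side Effect-Drug Link Prediction by NMF-Seeded Heat Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between drug side effects and drugs on a
    heterogeneous graph built from a side-effect-drug bipartite graph and a
    weighted drug-drug semantic similarity graph. Observed links are first
    completed by nonnegative matrix factorization (multiplicative updates on
    the Frobenius objective); each side effect's completed association row
    then seeds a heat-diffusion process on the similarity graph, computed
    either through the exact matrix exponential kernel or a discrete
    sparse-iteration approximation. Includes classical link-prediction
    baselines (common neighbors, Jaccard, Adamic/Adar, resource allocation,
    truncated Katz, personalized PageRank, random), cross-validated AUPR
    evaluation with paired t-tests, a degree-preserving permutation test,
    training-fraction sweeps, and a latent-factor synthetic data generator
    for offline benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
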