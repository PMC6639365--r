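# heatlink

Predicting unknown links between drug **side effects** and **drugs** from a
heterogeneous graph: a bipartite graph of known side-effect–drug associations
plus a weighted drug–drug semantic similarity graph (e.g. cosine similarities
of word-embedding vectors). The package is aimed at computational
pharmacology / cheminformatics work where laboratory confirmation of adverse
drug reactions is expensive and a ranked list of candidate associations is
the useful deliverable.

## The model

Let `Y ∈ {0,1}^{m×n}` be the biadjacency matrix of `m` side effects by `n`
drugs (`y_ij = 1` for a known association), and let `G = (V, E, W)` be the
undirected weighted drug–drug similarity graph.

1. **Matrix completion.** `Y` is factorized as `Y ≈ Ŷ = S Dᵀ` with
   `S ∈ R^{m×r}_{≥0}`, `D ∈ R^{n×r}_{≥0}`, minimizing `‖Y − S Dᵀ‖²_F`
   subject to `S, D ≥ 0` (Lee–Seung multiplicative updates). Every cell —
   observed or not — receives a nonnegative association weight
   `ŷ_ij = s_iᵀ d_j`.

2. **Heat diffusion.** Each side effect's completed row `f(0) = Ŷ[i, ]` seeds
   a diffusion process on the similarity graph,

   `f(1) = e^{αH} f(0)`,

   where the heat matrix `H` has `H_ij = w_ji / d_j` for edges `(v_j, v_i)`
   (with `d_j` the weighted degree) and `H_ii = −τ_i` (`τ_i = 1` iff node i
   has an edge). Non-isolated columns of `H` sum to zero, so total heat is
   conserved. In production the kernel is approximated by
   `f(1) = (I + α/M · H)^M f(0)` computed as `M` sparse matrix–vector
   products; defaults `α = 1`, `M = 30`.

The diffused rows are the prediction scores: drugs semantically close to a
side effect's known drugs heat up even without an observed link. Baseline
scorers (common neighbors, Jaccard, Adamic/Adar, resource allocation,
truncated Katz, personalized PageRank, random) and the full evaluation
machinery (stratified k-fold AUPR cross-validation, paired t-tests,
degree-preserving permutation test, training-fraction sweep) are included,
along with a planted latent-factor synthetic data generator so everything
runs offline.

## Worked example

```r
library(heatlink)
toy <- make_toy_network()                  # 3 side effects x 6 drugs
fit <- heatlink(toy$Y, toy$G, rank = 2, seed = 42)
fit
#> NMF-seeded heat-diffusion link predictor
#>   3 side effects x 6 drugs, 7 observed links
#>   NMF rank 2 (15 iterations, objective 1.382)
#>   diffusion: alpha = 1, M = 30 on 9 similarity edges

predict(fit, top_n = 2)
#>       side_effect drug     score rank
#> 1     se_headache   d5 0.3478043    1
#> 2     se_headache   d6 0.3255876    2
#> 3 se_stomach_ache   d1 0.2455578    1
#> 4 se_stomach_ache   d6 0.2356075    2
#> 5       se_nausea   d3 0.5852555    1
#> 6       se_nausea   d2 0.4217540    2
```

`predict()` ranks only pairs with no observed link: for each side effect the
drugs are ordered by diffused heat — e.g. `se_nausea`'s top candidate is
`d3`, the strongest similarity neighbor of its known drugs. `summary(fit)`
reports the NMF fit error and verifies per-row heat conservation;
`fitted(fit)` returns the full score matrix, and `write_predictions()`
exports ranked top-k lists as TSV.

Real data come in through `read_bipartite_edges()` (side-effect–drug TSV)
and either `read_similarity_edges()` (weighted drug–drug TSV) or
`read_word2vec_text()` + `build_similarity_from_embeddings()` (cosine
similarities of embedding vectors; negative cosines never become edges).

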