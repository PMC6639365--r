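---
title: "Methods: NMF-seeded heat diffusion for side-effect–drug link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMF-seeded heat diffusion for side-effect-drug link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatlink)
```

## The problem and the model

Known associations between side effects and drugs form a sparse bipartite
graph: `m` side effects (rows) by `n` drugs (columns), `y_ij = 1` when the
association has been reported. The prediction task is to rank the unobserved
(side effect, drug) pairs by how likely they are to be true associations. A
second source of evidence is a weighted drug–drug similarity graph whose
edge weights quantify how semantically related two drugs are (in practice,
cosine similarities between word-embedding vectors of the drug names). The
modeling assumption that links the two graphs is that *similar drugs tend to
share side effects*.

`heatlink()` combines the two graphs in two stages:

1. **Nonnegative matrix completion.** `Y ≈ Ŷ = S Dᵀ` with elementwise
   nonnegative `S` (m × r) and `D` (n × r), minimizing the squared Frobenius
   error over *all* cells — zeros are treated as weakly observed zeros, i.e.
   plain NMF on the full 0/1 matrix rather than a masked factorization over
   observed cells only. The reconstruction assigns every cell a nonnegative
   weight; observed cells generally score high and unobserved cells score in
   proportion to how well they fit the latent factor structure.

2. **Heat diffusion.** Each side effect's completed row is a vector of
   initial heat on the drug graph's nodes and is transported by the kernel
   `e^{αH}`. Drugs connected by high-weight edges exchange heat quickly, so
   a drug with no observed link but strong similarity to a side effect's
   known drugs ends up with a high diffused score.

The two stages are complementary: completion supplies graded seed weights
(including for the observed cells, which a 0/1 matrix cannot), and diffusion
injects the similarity evidence that factorization of the bipartite graph
alone cannot see.

## The heat matrix and its conventions

For an undirected weighted graph, the heat matrix used here is

* `H[i, j] = w_ji / d_j` when `(v_j, v_i)` is an edge, and
* `H[i, i] = −τ_i`, where `τ_i = 1` iff node `i` has at least one incident
  edge,

with `d_j` the **weighted** degree (the sum of incident edge weights). With
this reading every non-isolated column of `H` sums to zero, which gives the
two properties the implementation asserts on every call:

* **Heat conservation** — `1ᵀ e^{αH} = 1ᵀ`, so `sum(f(1)) = sum(f(0))`
  exactly; isolated nodes have zero rows and columns and simply keep their
  heat.
* **Nonnegativity** — for the discrete operator (below) with `α ≤ M`, the
  propagation matrix `I + (α/M) H` is entrywise nonnegative, so nonnegative
  seeds stay nonnegative.

Interpreting `d` as the unweighted edge count is available through
`build_heat_matrix(g, degree = "unweighted")`, but it loses exact column-sum
zero on weighted graphs and with it exact conservation, so the weighted
reading is the default. τ is defined by *incident* edges because the graph
is undirected; the outgoing/incoming distinction of directed formulations
is vacuous here.

## Exact kernel versus discrete approximation

`diffuse_exact()` computes the dense matrix exponential (`Matrix::expm`),
an O(n³) operation that is practical only on small graphs; it is capped at
`exact_cap = 2000` nodes and serves as the reference implementation and test
oracle. The production path, `diffuse_discrete()`, uses

`f(1) = (I + α/M · H)^M f(0)`

applied as `M` successive sparse matrix–vector products — the dense power is
never formed, so one seed vector costs O(M·|E|). The approximation error
decays as O(1/M); the test suite verifies that the sup-norm gap to the exact
kernel shrinks monotonically over `M ∈ {1, 10, 30, 100, 1000}` and is below
0.05 at the default `M = 30` on random weighted graphs up to 50 nodes.

**Defaults.** `α = 1` (thermal conductivity: how fast heat spreads) and
`M = 30`. These are the standard practical settings for this family of
diffusion kernels; `α` must not exceed `M` or the propagation matrix
acquires a negative diagonal, which the code rejects.

## NMF: algorithm and numerical choices

* **Updates**: Lee–Seung multiplicative updates for the Frobenius objective,
  chosen because they guarantee a monotonically non-increasing objective —
  an invariant the test suite asserts (to 1e−10 floating-point slack) on
  every run.
* **Initialization**: uniform(0, 1) entries scaled by `sqrt(mean(Y)/r)` so
  the initial product matches the data's mean scale; the RNG seed is an
  explicit argument and two runs with the same seed are bitwise identical.
* **Stopping**: relative objective decrease below `rel_tol = 1e−6` or
  `max_iter = 500` sweeps. For *exact* low-rank recovery experiments the
  suite runs with `rel_tol = 1e−14` and tens of thousands of sweeps, because
  multiplicative updates approach exact factorizations sublinearly; typical
  link-prediction use needs nothing near that.
* **Denominator guard**: `eps = 1e−9` is added to the update denominators;
  it breaks exact scale equivariance by a relative margin far below the 1%
  the scale-consistency test allows.
* **Zeros**: unobserved cells enter the objective as observed zeros. This
  matches a squared-error objective summed over all cells and is what makes
  the completed matrix sparse-ish and nonnegative without extra
  regularization. A consequence worth knowing: in held-out evaluations the
  removed links are *trained on as zeros*, which depresses their
  reconstructed scores and biases inner-CV rank selection toward small
  ranks (see *Known limitations*).

`select_rank()` chooses the rank by masking observed links inside the
training matrix (`inner_folds` groups), refactorizing, and scoring recovery
of the masked links against an equal-count sample of never-observed cells by
AUPR; ties go to the smallest rank. The negative sample is seeded per fold
and shared across candidate ranks so the comparison is paired.

## Seeding choice for the diffusion stage

The default seed vector is the *full* completed row of `Ŷ` — unobserved
cells contribute whatever weight the factorization assigned them. The
alternative, exposed as `heatlink(..., seed_known_only = TRUE)`, zeroes the
completed matrix outside the observed links so only known associations carry
heat. The full-row default is the more informative choice (the completed
weights are exactly what the factorization stage exists to provide), and the
switch makes the conservative reading available for sensitivity analysis.

## Evaluation machinery

* **Folds** (`split_folds`): the unit of partitioning is the *link*,
  stratified per side-effect row. Removing whole side effects would zero
  out test rows, leaving the factorization nothing to seed them with.
  Assignment runs per-row round-robin while continuing a single global
  pointer (rows visited in seeded random order), so per-row *and* overall
  fold sizes each differ by at most one.
* **AUPR** (`aupr`): scores are ranked descending; tied scores form one
  threshold step; the curve is anchored at (recall 0, precision 1) and
  integrated by the trapezoidal rule. AUPR is preferred over ROC-AUC here
  because candidate sets are extremely imbalanced (a few held-out positives
  against all never-observed pairs).
* **Candidates** (`cross_validate`): per side effect, every drug without a
  training link; positives are the fold's held-out links, negatives the
  never-observed pairs, pooled into one AUPR per fold per method. No
  negative subsampling is used at package scale.
* **Method comparison**: two-sided paired t-tests on the per-fold AUPR
  vectors (k − 1 degrees of freedom), with an explicit error on
  zero-variance differences.
* **Permutation test** (`permutation_pvalues`): the drug graph is
  randomized by degree-preserving double-edge swaps (weights travel with
  their edges), the *same* seed vectors are rediffused, and
  `p = Ω/N` counts randomized scores *strictly* greater than the actual one
  — ties do not count against the actual score.
* **Training-fraction sweep** (`training_fraction_sweep`): keeps a random
  fraction of links for training and tests on the rest. Note that the
  candidate-set prevalence changes with the fraction (fewer held-out
  positives against the same negatives at high fractions), so raw AUPR
  values are not comparable across very different fractions at small matrix
  sizes; at realistic scales (hundreds of thousands of cells) the effect is
  negligible.

## The synthetic generator

`generate_synthetic()` emulates the structure the method assumes:

* nonnegative latent factors `S*` (m × r) and `D*` (n × r) drawn from
  seeded exponential(1) distributions; `Y_true = S* D*ᵀ`;
* positives: exactly `floor(density · m · n)` cells — each row's single
  top-scoring cell first (so every side effect has at least one link), then
  the globally top-scoring remaining cells. Top-cell selection rather than
  Bernoulli sampling makes the density exact and the dataset a
  deterministic function of the seed. A fraction of positives
  (`held_out_frac`, default 10%) is removed from the observed matrix for
  benchmarking, with one protected link per row so no row empties;
* similarity graph: cosine similarities of the rows of `D*`, optionally
  perturbed by symmetric Gaussian noise (`sim_noise`), non-positive
  weights dropped. Because links and similarities derive from the *same*
  drug factors, similar drugs share side effects by construction.

What it does *not* emulate: the empirical degree distribution of real
pharmacovigilance databases, name-matching noise between drug labels and
embedding vocabularies, and — importantly — the *spread* of real embedding
cosines. Cosines of nonnegative low-dimensional factors are all large and
positive, so the noiseless synthetic similarity graph is complete with
relatively uniform weights. Two consequences follow for interpreting test
results (both are verified behaviors, not speculation):

* at `α = 1` the kernel mixes such a dense graph strongly, so on
  *noiseless exact-rank* synthetic data the diffusion stage adds little
  over a correctly specified NMF — its measured benefit over NMF-only
  fluctuates around zero there, while both dominate diffusion-only and the
  random baseline by an order of magnitude;
* degree-preserving edge swaps cannot move a complete graph (every proposal
  collides with an existing edge), so permutation-test studies need a graph
  sparse enough to randomize — either `sim_noise > 0` or an explicit sparse
  graph.

Problem sizes used by the test suite and acceptance script — 50 × 40
matrices at density 0.12 with rank 3, graphs up to 50 nodes, 10-fold
cross-validation, 200 graph randomizations — are the package's chosen
desk-scale study conditions; all machinery accepts larger inputs.

## Degenerate inputs and tie-breaking

* Empty similarity graphs produce a zero heat matrix (with a warning):
  diffusion is the identity.
* Self-loops, non-positive weights and (in embedding mode) non-positive
  cosines never create edges; conflicting duplicate edge weights are an
  error rather than a silent choice.
* Drugs missing from the embedding vocabulary stay as isolated nodes so the
  similarity graph remains index-aligned with the biadjacency columns; drug
  names are matched to tokens case-insensitively after trimming, one token
  per drug.
* Ranked outputs break score ties by ascending drug label, making files
  byte-reproducible.
* Adamic/Adar terms with shared-neighbor degree ≤ 1 contribute zero (their
  `1/log` weight is undefined), with a warning.
* Katz is truncated at `l_max = 4` with `β = 0.005` by default and counts
  walks, not simple paths; personalized PageRank uses restart 0.15,
  tolerance 1e−8, and returns dangling-walk mass to the query node.

## Known limitations

* **Rank selection on thresholded low-rank data is biased low.** Because
  plain NMF trains held-out cells as zeros, and because binarizing a dense
  nonnegative low-rank matrix retains mostly first-factor information,
  inner-CV rank selection tends to choose ranks below a planted rank. On
  real, genuinely multi-factor binary data the bias is milder, but the
  selected rank should be read as "best for held-out link recovery", not as
  an estimate of latent dimensionality.
* **Diffusion strength is not adapted to graph density.** `α = 1` is a
  fixed default; on very dense similarity graphs it can over-smooth. The
  parameter is exposed, and conservation/nonnegativity hold for any
  `0 < α ≤ M`.
* **Permutation p-values share one set of randomized graphs across all
  pairs**, so they are correlated between pairs; the histogram of p-values
  under a null condition is approximately, not exactly, uniform at a few
  hundred randomizations.
* The model scores single drugs only; associations that arise from
  drug–drug *interactions* (polypharmacy) are outside its scope.
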