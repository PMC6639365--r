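test_that("neighborhood metrics match hand set arithmetic", {
  # x1-y1, x1-y2, x2-y2, x2-y3 plus similarity y1-y2: N(x1) = {y1, y2},
  # N(y3) = {x2}; shared neighbor structure checked against hand values
  bip <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3)
  sim <- matrix(0, 3, 3); sim[1, 2] <- sim[2, 1] <- 0.9
  g <- make_combined(bip, sim)

  # N(x1) = {y1, y2}; N(y2) = {x1, x2, y1} via the similarity edge:
  # shared z = y1 with |N(y1)| = 2, so CN = 1, Jaccard = 1/4, RA = 1/2
  expect_equal(neighborhood_score(g, "x1", "y2", "common_neighbors"), 1)
  expect_equal(neighborhood_score(g, "x1", "y2", "jaccard"), 1 / 4)
  expect_equal(neighborhood_score(g, "x1", "y2", "resource_allocation"), 1 / 2)
  adj <- full_adjacency(bip, sim)
  expect_equal(neighborhood_score(g, "x1", "y2", "common_neighbors"),
               oracle_neighborhood(adj, 1, 4, "common_neighbors"))

  # disjoint neighborhoods give 0 for all four metrics
  bip2 <- matrix(c(1, 0, 0, 1), 2, 2)
  g2 <- make_combined(bip2, matrix(0, 2, 2))
  for (mt in c("common_neighbors", "jaccard", "adamic_adar", "resource_allocation")) {
    expect_equal(neighborhood_score(g2, "x1", "y2", mt), 0)
  }

  # shared neighbor z with |N(z)| = 2: AA = 1/ln 2, RA = 1/2
  bip3 <- matrix(c(1, 1), 2, 1)  # x1-y1, x2-y1
  g3 <- make_combined(bip3, matrix(0, 1, 1))
  expect_equal(neighborhood_score(g3, "x1", "x2", "adamic_adar"), 1 / log(2),
               tolerance = 1e-12)
  expect_equal(neighborhood_score(g3, "x1", "x2", "resource_allocation"), 0.5)
})

test_that("all four neighborhood metrics match the oracle on exhaustive 4-node graphs", {
  # 2 side effects x 2 drugs: 4 bipartite bits x 2 similarity bits = 32 graphs
  for (code in 0:31) {
    bits <- as.integer(intToBits(code))[1:5]
    bip <- matrix(bits[1:4], 2, 2)
    sim <- matrix(0, 2, 2)
    if (bits[5] == 1) { sim[1, 2] <- sim[2, 1] <- 0.7 }
    g <- make_combined(bip, sim)
    adj <- full_adjacency(bip, sim)
    for (mt in c("common_neighbors", "jaccard", "adamic_adar", "resource_allocation")) {
      got <- suppressWarnings(neighborhood_score(g, "x1", "y2", mt))
      expect_equal(got, oracle_neighborhood(adj, 1, 4, mt), tolerance = 1e-8)
      # symmetry on the undirected graph
      expect_equal(got, suppressWarnings(neighborhood_score(g, "y2", "x1", mt)),
                   tolerance = 1e-12)
    }
  }
})

test_that("Katz matches single-term and two-hop hand values", {
  bip <- matrix(c(1, 0), 1, 2)  # x1-y1 only
  sim <- matrix(0, 2, 2); sim[1, 2] <- sim[2, 1] <- 0.5
  g <- make_combined(bip, sim)
  # adjacent pair, l_max = 1
  expect_equal(katz_score(g, "x1", "y1", beta = 0.1, l_max = 1), 0.1)
  # x1 - y1 - y2: one walk of length 2, no direct edge
  expect_equal(katz_score(g, "x1", "y2", beta = 0.1, l_max = 2), 0.01,
               tolerance = 1e-12)
})

test_that("Katz equals brute-force walk enumeration and is monotone in walk length", {
  set.seed(31)
  for (rep in 1:25) {
    m <- sample(1:2, 1); n <- sample(2:3, 1)
    bip <- matrix(rbinom(m * n, 1, 0.5), m, n)
    sim <- matrix(0, n, n)
    ut <- upper.tri(sim)
    sim[ut] <- rbinom(sum(ut), 1, 0.5) * runif(sum(ut), 0.2, 1)
    sim <- sim + t(sim)
    g <- make_combined(bip, sim)
    adj <- full_adjacency(bip, sim)
    x <- 1; y <- m + sample(n, 1)
    for (lm in 2:4) {
      expect_equal(suppressWarnings(katz_score(g, "x1", sprintf("y%d", y - m),
                                               beta = 0.2, l_max = lm)),
                   oracle_katz(adj, x, y, 0.2, lm), tolerance = 1e-8)
    }
    k3 <- suppressWarnings(katz_score(g, "x1", sprintf("y%d", y - m), beta = 0.2, l_max = 3))
    k4 <- suppressWarnings(katz_score(g, "x1", sprintf("y%d", y - m), beta = 0.2, l_max = 4))
    expect_gte(k4, k3)
  }
})

test_that("personalized PageRank matches the closed form and the linear-solve oracle", {
  # one side effect linked to one drug: 2-node chain
  bip <- matrix(1, 1, 1)
  g <- make_combined(bip, matrix(0, 1, 1))
  pv <- ppr_score(g, "x1", restart = 0.15)
  expect_equal(unname(pv["x1"]), 0.15 / (1 - 0.85^2), tolerance = 1e-7)
  expect_equal(sum(pv), 1, tolerance = 1e-10)

  set.seed(17)
  for (rep in 1:20) {
    m <- sample(2:3, 1); n <- sample(3:5, 1)
    repeat {
      bip <- matrix(rbinom(m * n, 1, 0.6), m, n)
      if (all(rowSums(bip) > 0) && all(colSums(bip) > 0)) break
    }
    sim <- matrix(0, n, n); ut <- upper.tri(sim)
    sim[ut] <- rbinom(sum(ut), 1, 0.4); sim <- sim + t(sim)
    g <- make_combined(bip, sim)
    adj <- full_adjacency(bip, sim)
    pv <- ppr_score(g, "x1", restart = 0.15, tol = 1e-12)
    expect_equal(unname(pv), unname(oracle_ppr(adj, 1, 0.15)), tolerance = 1e-8)
  }
})

test_that("PageRank restart limit, positivity, and error paths behave", {
  bip <- matrix(c(1, 1, 0, 1), 2, 2)
  sim <- matrix(0, 2, 2); sim[1, 2] <- sim[2, 1] <- 1
  g <- make_combined(bip, sim)
  pv <- ppr_score(g, "x1", restart = 0.999999)
  expect_equal(unname(pv[c("x1")]), 1, tolerance = 1e-4)
  pv2 <- ppr_score(g, "x1", restart = 0.15)
  expect_true(all(pv2 > 0))  # connected graph

  bip_iso <- matrix(c(1, 0, 0, 0), 2, 2)
  g_iso <- make_combined(bip_iso, matrix(0, 2, 2))
  expect_error(ppr_score(g_iso, "x2"), "isolated")
})

test_that("random scorer is reproducible and handles empty input", {
  pairs <- data.frame(row = 1:5, col = 1:5)
  expect_identical(random_score(pairs, seed = 9), random_score(pairs, seed = 9))
  expect_false(all(random_score(pairs, seed = 9) == random_score(pairs, seed = 10)))
  expect_identical(random_score(pairs[0, ], seed = 1), numeric(0))
})

test_that("combined graph construction enforces alignment and disjoint labels", {
  Y <- bipartite_adjacency(c("s1", "s2"), c("d1", "d2"))
  G <- similarity_graph(c("d1", "d2"), data.frame(from = "d1", to = "d2", weight = 1))
  g <- combined_graph(Y, G)
  expect_equal(length(g$labels), 4)
  G_bad <- similarity_graph(c("d2", "d1"), data.frame(from = "d1", to = "d2", weight = 1))
  expect_error(combined_graph(Y, G_bad), "same order")
  Y_bad <- bipartite_adjacency(c("d1", "s2"), c("d1", "d2"),
                               row_labels = c("d1", "s2"))
  expect_error(combined_graph(Y_bad, G), "disjoint")
})
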