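test_that("fold splitting partitions links with per-row and global balance", {
  # 10 side effects x 10 links each = 100 links, k = 10
  Y <- Matrix::sparseMatrix(i = rep(1:10, each = 10), j = rep(1:10, 10), x = 1,
                            dimnames = list(sprintf("s%02d", 1:10), sprintf("d%02d", 1:10)))
  sp <- split_folds(Y, 10, seed = 1)
  sizes <- tabulate(sp$assignments$fold, 10)
  expect_equal(sizes, rep(10L, 10))
  # stratification: each row contributes exactly one link per fold
  per_row <- table(sp$assignments$row, sp$assignments$fold)
  expect_true(all(per_row == 1))
})

test_that("fold splitting is deterministic per seed and seed-sensitive", {
  ds <- generate_synthetic(m = 20, n = 15, r_true = 2, link_density = 0.15, seed = 2)
  s1 <- split_folds(ds$Y_obs, 5, seed = 3)
  s2 <- split_folds(ds$Y_obs, 5, seed = 3)
  s3 <- split_folds(ds$Y_obs, 5, seed = 4)
  expect_identical(s1$assignments, s2$assignments)
  expect_false(identical(s1$assignments$fold, s3$assignments$fold))
  # disjoint and exhaustive
  expect_equal(nrow(s1$assignments), Matrix::nnzero(ds$Y_obs))
  expect_true(all(s1$assignments$fold %in% 1:5))
  # per-row fold sizes differ by at most 1
  tab <- table(s1$assignments$row, s1$assignments$fold)
  expect_true(all(apply(tab, 1, function(x) diff(range(x))) <= 1))
  expect_error(split_folds(ds$Y_obs, 10000), "more folds")
})

test_that("AUPR matches hand values under the trapezoidal threshold rule", {
  expect_equal(aupr(c(0.9, 0.1), c(1, 0))$aupr, 1.0)
  expect_equal(aupr(c(0.1, 0.9), c(1, 0))$aupr, 0.25)
  expect_error(aupr(c(1, 2), c(1, 1)), "positive and one negative")
  pc <- aupr(c(0.3, 0.2, 0.2, 0.1), c(1, 0, 1, 0))
  expect_true(all(diff(pc$recall) >= 0))
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))
})

test_that("AUPR equals the exhaustive threshold oracle on all short inputs", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    scores <- sample(c(runif(n), round(runif(n), 1)), n)  # force occasional ties
    labels <- integer(n)
    while (sum(labels) %in% c(0, n)) labels <- rbinom(n, 1, 0.5)
    expect_equal(aupr(scores, labels)$aupr, oracle_aupr(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUPR is invariant under strictly monotone score transforms", {
  set.seed(14)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  a0 <- aupr(scores, labels)$aupr
  expect_equal(aupr(exp(3 * scores), labels)$aupr, a0, tolerance = 1e-12)
  expect_equal(aupr(rank(scores), labels)$aupr, a0, tolerance = 1e-12)
})

test_that("paired t-test matches the closed form and rejects degenerate input", {
  a <- c(0.5, 0.6, 0.55, 0.62, 0.58, 0.61, 0.54, 0.59, 0.6, 0.57)
  b <- a - c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1) * 0.1 - 0.2
  tt <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) * sqrt(10) / sd(d)
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 9)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), 9), tolerance = 1e-12)
  expect_error(paired_ttest(a, a), "degenerate")
  # strongly one-sided differences are highly significant
  tt2 <- paired_ttest(a + 0.2 + 0.001 * seq_along(a), a)
  expect_lt(tt2$p, 0.001)
})

test_that("cross-validation reproduces chance level for the random scorer", {
  ds <- generate_synthetic(m = 25, n = 20, r_true = 2, link_density = 0.15, seed = 6)
  sp <- split_folds(ds$Y_obs, 5, seed = 6)
  cv <- cross_validate(ds$Y_obs, ds$G, c("random", "random"), sp)
  # identical method listed twice gives identical per-fold vectors
  expect_equal(unname(cv$aupr[, 1]), unname(cv$aupr[, 2]))
  # chance level ~ candidate-set prevalence (positives / candidates per fold)
  prev <- mean(vapply(1:5, function(f) {
    held <- sum(sp$assignments$fold == f)
    held / (sum(as.matrix(ds$Y_obs) == 0) + held)
  }, numeric(1)))
  se <- cv$sd[1] / sqrt(5)
  expect_lt(abs(cv$mean[1] - prev), 3 * se + 0.02)
})

test_that("the NMF-diffusion pipeline clearly beats chance on planted data", {
  ds <- generate_synthetic(seed = 11)
  sp <- split_folds(ds$Y_obs, 5, seed = 11)
  cv <- cross_validate(ds$Y_obs, ds$G, c("hd_nmf", "random"), sp, rank = 3)
  prev <- cv$mean["random"]
  expect_gt(cv$mean["hd_nmf"], 5 * prev)
  tt <- paired_ttest(cv$aupr[, "hd_nmf"], cv$aupr[, "random"])
  expect_lt(tt$p, 0.05)
})

test_that("cross-validation validates methods and fold compatibility", {
  ds <- generate_synthetic(m = 15, n = 12, r_true = 2, link_density = 0.2, seed = 3)
  sp <- split_folds(ds$Y_obs, 3, seed = 1)
  expect_error(cross_validate(ds$Y_obs, ds$G, "nosuch", sp), "unknown method")
})

test_that("degree-preserving randomization preserves the degree multiset exactly", {
  g1 <- similarity_graph(c("a", "b"), data.frame(from = "a", to = "b", weight = 1))
  expect_identical(degree_preserving_randomize(g1, seed = 5)$edges, g1$edges)

  for (s in 1:10) {
    g <- rand_sim_graph(sample(5:15, 1), 0.4, seed = 300 + s)
    gr <- degree_preserving_randomize(g, seed = s)
    deg <- function(gg) {
      d <- integer(gg$n)
      tb <- table(c(gg$edges$i, gg$edges$j))
      d[as.integer(names(tb))] <- as.integer(tb)
      d
    }
    expect_equal(deg(gr), deg(g))
    expect_equal(sort(gr$edges$w), sort(g$edges$w))  # weights travel, none lost
    expect_equal(nrow(gr$edges), nrow(g$edges))
  }
})

test_that("randomization explores multiple configurations when the swap space allows", {
  # two disjoint edges can swap into crossed pairings
  g <- similarity_graph(c("a", "b", "c", "d"),
                        data.frame(from = c("a", "c"), to = c("b", "d"),
                                   weight = c(0.5, 0.7)))
  seen <- unique(vapply(1:50, function(s) {
    e <- degree_preserving_randomize(g, seed = s)$edges
    paste(paste(e$i, e$j, sep = "-"), collapse = ",")
  }, character(1)))
  expect_gt(length(seen), 1)

  # 5-cycle has several degree-preserving configurations
  lab <- sprintf("v%d", 1:5)
  g5 <- similarity_graph(lab, data.frame(from = lab, to = lab[c(2:5, 1)],
                                         weight = 1))
  seen5 <- unique(vapply(1:30, function(s) {
    e <- degree_preserving_randomize(g5, seed = s)$edges
    paste(paste(e$i, e$j, sep = "-"), collapse = ",")
  }, character(1)))
  expect_gt(length(seen5), 1)
})

test_that("permutation p-values are exact multiples of 1/N with correct boundaries", {
  ds <- generate_synthetic(m = 12, n = 10, r_true = 2, link_density = 0.2, seed = 9)
  pairs <- data.frame(row = c(1, 2, 3), col = c(1, 2, 3))
  pt <- permutation_pvalues(ds$Y_obs, ds$G, pairs, N = 20, seed = 2, rank = 2)
  expect_equal(pt$p, pt$omega / 20)
  expect_true(all(pt$omega >= 0 & pt$omega <= 20))
  expect_identical(pt$p, pt$omega / 20)
  expect_true(all(pt$omega == round(pt$omega)))
})

test_that("training-fraction sweep is deterministic and validates fractions", {
  ds <- generate_synthetic(m = 20, n = 15, r_true = 2, link_density = 0.15, seed = 5)
  s1 <- training_fraction_sweep(ds$Y_obs, ds$G, c(0.5, 0.9), repeats = 1,
                                seed = 7, rank = 2)
  s2 <- training_fraction_sweep(ds$Y_obs, ds$G, c(0.5, 0.9), repeats = 1,
                                seed = 7, rank = 2)
  expect_identical(s1, s2)
  expect_equal(s1$fraction, c(0.5, 0.9))
  expect_error(training_fraction_sweep(ds$Y_obs, ds$G, 0.001, repeats = 1),
               "zero training links")
})

test_that("a 90% training fraction lands near the 10-fold cross-validation mean", {
  ds <- generate_synthetic(seed = 21)
  sp <- split_folds(ds$Y_obs, 10, seed = 21)
  cv <- cross_validate(ds$Y_obs, ds$G, "hd_nmf", sp, rank = 3)
  sw <- training_fraction_sweep(ds$Y_obs, ds$G, 0.9, repeats = 3, seed = 21, rank = 3)
  expect_lt(abs(sw$mean_aupr - cv$mean["hd_nmf"]),
            4 * max(cv$sd["hd_nmf"], 0.02))
})
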