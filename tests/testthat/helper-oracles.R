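# Independent brute-force oracles and small fixture generators used across
# the suite. These deliberately share no code with the package internals.

# Random weighted similarity graph with at least one edge.
rand_sim_graph <- function(n, p = 0.4, seed = 1, labels = sprintf("n%02d", seq_len(n))) {
  set.seed(seed)
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  pairs <- pairs[keep, , drop = FALSE]
  similarity_graph(labels,
                   data.frame(from = labels[pairs[, 1]], to = labels[pairs[, 2]],
                              weight = runif(nrow(pairs), 0.1, 1)),
                   quiet = TRUE)
}

# Dense heat matrix assembled entry by entry straight from the definition.
oracle_heat_matrix <- function(g) {
  n <- g$n
  H <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(g$edges))) {
    W[g$edges$i[k], g$edges$j[k]] <- g$edges$w[k]
    W[g$edges$j[k], g$edges$i[k]] <- g$edges$w[k]
  }
  d <- rowSums(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        H[i, i] <- if (d[i] > 0) -1 else 0
      } else if (W[j, i] > 0) {
        H[i, j] <- W[j, i] / d[j]
      }
    }
  }
  H
}

# AUPR by explicit enumeration of every distinct-score threshold.
oracle_aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  pts <- t(vapply(thr, function(th) {
    sel <- scores >= th
    c(recall = sum(labels[sel]) / P,
      precision = sum(labels[sel]) / sum(sel))
  }, numeric(2)))
  r <- c(0, pts[, "recall"])
  p <- c(1, pts[, "precision"])
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

# Walk counting by explicit recursion for the truncated Katz index.
oracle_katz <- function(adj, x, y, beta, l_max) {
  n_walks <- function(from, len) {
    if (len == 0) return(as.numeric(from == y))
    sum(vapply(which(adj[from, ] > 0), function(nb) n_walks(nb, len - 1), numeric(1)))
  }
  sum(vapply(seq_len(l_max), function(l) beta^l * n_walks(x, l), numeric(1)))
}

# Personalized PageRank by direct linear solve of (I - (1-r) P') pi = r e_x.
oracle_ppr <- function(adj, x, restart) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  P <- adj / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0
  e_x <- numeric(n); e_x[x] <- 1
  solve(diag(n) - (1 - restart) * t(P), restart * e_x)
}

# Neighborhood metrics from explicit neighbor sets.
oracle_neighborhood <- function(adj, x, y, metric) {
  Nx <- which(adj[x, ] > 0)
  Ny <- which(adj[y, ] > 0)
  z <- intersect(Nx, Ny)
  deg <- rowSums(adj > 0)
  switch(metric,
    common_neighbors = length(z),
    jaccard = if (length(union(Nx, Ny)) == 0) 0 else
      length(z) / length(union(Nx, Ny)),
    adamic_adar = sum(vapply(z, function(zz)
      if (deg[zz] > 1) 1 / log(deg[zz]) else 0, numeric(1))),
    resource_allocation = sum(vapply(z, function(zz)
      if (deg[zz] > 0) 1 / deg[zz] else 0, numeric(1)))
  )
}

# Small combined bipartite + similarity graph from explicit edge flags.
# bip: m x n 0/1 matrix; sim: n x n symmetric 0/1 (or weighted) matrix.
make_combined <- function(bip, sim) {
  m <- nrow(bip); n <- ncol(bip)
  se <- sprintf("x%d", seq_len(m))
  dr <- sprintf("y%d", seq_len(n))
  dimnames(bip) <- list(se, dr)
  ut <- which(upper.tri(sim) & sim > 0, arr.ind = TRUE)
  G <- similarity_graph(dr, data.frame(from = dr[ut[, 1]], to = dr[ut[, 2]],
                                       weight = sim[ut]), quiet = TRUE)
  combined_graph(Matrix::Matrix(bip, sparse = TRUE), G)
}

# Full undirected binarized adjacency of a combined graph (oracle side).
full_adjacency <- function(bip, sim) {
  m <- nrow(bip); n <- ncol(bip)
  A <- matrix(0, m + n, m + n)
  A[seq_len(m), m + seq_len(n)] <- (bip > 0) + 0
  A[m + seq_len(n), seq_len(m)] <- t((bip > 0) + 0)
  A[m + seq_len(n), m + seq_len(n)] <- (sim > 0) + 0
  diag(A) <- 0
  A
}
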