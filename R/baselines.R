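#' Combine the bipartite and similarity graphs into one undirected graph
#'
#' The combined heterogeneous graph has one node per side effect and per drug;
#' its edges are the observed side-effect-drug links (weight 1) plus the
#' drug-drug similarity edges. The topological baseline scorers operate on its
#' binarized adjacency: two nodes are neighbors iff any positive-weight edge
#' joins them.
#'
#' @param Y 0/1 biadjacency matrix (side effects x drugs) with dimnames.
#' @param G [similarity_graph()] over the drugs, aligned to `colnames(Y)`.
#' @return Object of class `combined_graph`: list with `labels`
#'   (side effects then drugs), `type` ("side_effect"/"drug"), binarized
#'   sparse adjacency `A`, weighted adjacency `W`, and the row/col index
#'   ranges of the two node classes.
#' @export
combined_graph <- function(Y, G) {
  stopifnot(inherits(G, "similarity_graph"))
  if (is.null(rownames(Y)) || is.null(colnames(Y))) stop("Y must carry dimnames")
  if (!identical(colnames(Y), G$labels)) {
    stop("similarity graph nodes must equal colnames(Y), same order")
  }
  if (length(intersect(rownames(Y), colnames(Y)))) {
    stop("side-effect and drug label spaces must be disjoint")
  }
  m <- nrow(Y); n <- ncol(Y); N <- m + n
  labels <- c(rownames(Y), colnames(Y))
  links <- observed_links(Y)
  e <- G$edges
  ii <- c(links$row, m + links$col, m + e$i, m + e$j)
  jj <- c(m + links$col, links$row, m + e$j, m + e$i)
  ww <- c(rep(1, 2 * nrow(links)), e$w, e$w)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(N, N),
                            dimnames = list(labels, labels))
  A <- W
  A@x <- rep(1, length(A@x))
  structure(list(labels = labels,
                 type = rep(c("side_effect", "drug"), c(m, n)),
                 A = A, W = W,
                 se_idx = seq_len(m), drug_idx = m + seq_len(n)),
            class = "combined_graph")
}

#' @export
print.combined_graph <- function(x, ...) {
  cat(sprintf("combined_graph: %d side effects + %d drugs, %d undirected edges\n",
              length(x$se_idx), length(x$drug_idx), Matrix::nnzero(x$A) / 2))
  invisible(x)
}

node_index <- function(g, x) {
  k <- match(x, g$labels)
  if (is.na(k)) stop(sprintf("unknown node '%s'", x))
  k
}

#' Node-neighborhood link-prediction score for one pair
#'
#' Computes one of the classical neighborhood overlap statistics on the
#' combined graph's binarized, undirected neighborhoods N(.): common
#' neighbors `|N(x) ∩ N(y)|`; Jaccard `|N(x) ∩ N(y)| / |N(x) ∪ N(y)|` (0 when
#' the union is empty); Adamic/Adar `sum_z 1/ln|N(z)|` over shared neighbors z
#' (shared neighbors with `|N(z)| <= 1` contribute 0, with a warning, since
#' `ln 1 = 0`); resource allocation `sum_z 1/|N(z)|`.
#'
#' @param g A [combined_graph()].
#' @param x,y Node labels.
#' @param metric One of `"common_neighbors"`, `"jaccard"`, `"adamic_adar"`,
#'   `"resource_allocation"`.
#' @return The score (scalar).
#' @export
neighborhood_score <- function(g, x, y,
                               metric = c("common_neighbors", "jaccard",
                                          "adamic_adar", "resource_allocation")) {
  stopifnot(inherits(g, "combined_graph"))
  metric <- match.arg(metric)
  xi <- node_index(g, x); yi <- node_index(g, y)
  Nx <- which(g$A[xi, ] != 0)
  Ny <- which(g$A[yi, ] != 0)
  z <- intersect(Nx, Ny)
  deg <- Matrix::rowSums(g$A)
  switch(metric,
    common_neighbors = length(z),
    jaccard = {
      u <- length(union(Nx, Ny))
      if (u == 0) 0 else length(z) / u
    },
    adamic_adar = {
      if (any(deg[z] <= 1)) {
        warning("Adamic/Adar: shared neighbor(s) with degree <= 1 contribute 0")
      }
      ok <- z[deg[z] > 1]
      sum(1 / log(deg[ok]))
    },
    resource_allocation = sum(1 / deg[z][deg[z] > 0])
  )
}

#' Truncated Katz score for one pair
#'
#' `sum_{l=1}^{l_max} beta^l * (#walks of length l from x to y)` on the
#' combined graph's binarized adjacency; walks (not simple paths) are counted
#' through repeated sparse matrix-vector products.
#'
#' @param g A [combined_graph()].
#' @param x,y Node labels.
#' @param beta Attenuation factor in (0, 1); a warning is issued when
#'   `beta * max(degree) >= 1` (the untruncated series would diverge).
#' @param l_max Maximum walk length (>= 1; default 4).
#' @return The truncated Katz score.
#' @export
katz_score <- function(g, x, y, beta = 0.005, l_max = 4) {
  stopifnot(inherits(g, "combined_graph"), beta > 0, beta < 1, l_max >= 1)
  if (beta * max(Matrix::rowSums(g$A)) >= 1) {
    warning("beta * max degree >= 1: untruncated Katz series would diverge")
  }
  xi <- node_index(g, x); yi <- node_index(g, y)
  v <- numeric(length(g$labels)); v[xi] <- 1
  score <- 0
  for (l in seq_len(l_max)) {
    v <- as.numeric(g$A %*% v)
    score <- score + beta^l * v[yi]
  }
  score
}

#' Personalized PageRank vector for one query node
#'
#' Power iteration for the stationary distribution of a random walk on the
#' combined graph's binarized edges that restarts at `x` with probability
#' `restart` and otherwise moves to a uniformly random neighbor:
#' `pi = restart * e_x + (1 - restart) * P' pi`. Mass reaching a dangling
#' (isolated) node is returned to `x`. The result sums to 1;
#' `score(x, y) = pi[y]`.
#'
#' @param g A [combined_graph()].
#' @param x Query node label (must have at least one neighbor).
#' @param restart Restart probability in (0, 1); default 0.15.
#' @param tol Convergence tolerance on the sup-norm change (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return Named numeric vector over all nodes, summing to 1.
#' @export
ppr_score <- function(g, x, restart = 0.15, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(g, "combined_graph"), restart > 0, restart < 1)
  xi <- node_index(g, x)
  deg <- Matrix::rowSums(g$A)
  if (deg[xi] == 0) stop(sprintf("query node '%s' is isolated", x))
  N <- length(g$labels)
  # column-stochastic propagation: Pt = t(P), P = D^-1 A row-stochastic
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Pt <- Matrix::t(g$A * inv)  # scales rows of A by inv, then transpose
  e_x <- numeric(N); e_x[xi] <- 1
  pi_v <- e_x
  for (it in seq_len(max_iter)) {
    new_v <- restart * e_x + (1 - restart) * as.numeric(Pt %*% pi_v)
    # walker stranded on dangling nodes returns to the query node
    new_v[xi] <- new_v[xi] + (1 - sum(new_v))
    delta <- max(abs(new_v - pi_v))
    pi_v <- new_v
    if (delta < tol) {
      names(pi_v) <- g$labels
      return(pi_v)
    }
  }
  stop(sprintf("personalized PageRank did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

#' Seeded random scores for candidate pairs
#'
#' Assigns each candidate (side effect, drug) pair an independent
#' uniform(0, 1) score; the reference chance-level scorer.
#'
#' @param pairs Data frame (or matrix) of candidate pairs; only its row count
#'   is used.
#' @param seed Integer RNG seed.
#' @return Numeric vector of scores, one per pair (empty input gives an
#'   empty vector).
#' @export
random_score <- function(pairs, seed = 1) {
  n <- if (is.null(dim(pairs))) length(pairs) else nrow(pairs)
  if (n == 0) return(numeric(0))
  with_seed(seed, stats::runif(n))
}

# ---- matrix-level scorers used by cross_validate ---------------------------
# Each returns a full m x n matrix of scores for (side effect, drug) pairs.

baseline_score_matrix <- function(g, metric, katz_beta = 0.005, katz_lmax = 4,
                                  ppr_restart = 0.15, ppr_tol = 1e-8,
                                  ppr_max_iter = 1000) {
  A <- g$A
  se <- g$se_idx; dr <- g$drug_idx
  deg <- Matrix::rowSums(A)
  Bse <- A[se, , drop = FALSE]
  out <- switch(metric,
    common_neighbors = as.matrix((Bse %*% A)[, dr, drop = FALSE]),
    jaccard = {
      CN <- as.matrix((Bse %*% A)[, dr, drop = FALSE])
      un <- outer(deg[se], deg[dr], "+") - CN
      J <- ifelse(un > 0, CN / un, 0)
      J
    },
    adamic_adar = {
      wz <- ifelse(deg > 1, 1 / log(deg), 0)
      as.matrix((Bse %*% (A * wz))[, dr, drop = FALSE])
    },
    resource_allocation = {
      wz <- ifelse(deg > 0, 1 / deg, 0)
      as.matrix((Bse %*% (A * wz))[, dr, drop = FALSE])
    },
    katz = {
      X <- Bse
      acc <- NULL
      for (l in seq_len(katz_lmax)) {
        X <- X %*% A
        acc <- if (is.null(acc)) katz_beta^l * X else acc + katz_beta^l * X
      }
      as.matrix(acc[, dr, drop = FALSE])
    },
    ppr = {
      sc <- matrix(0, length(se), length(dr))
      for (k in seq_along(se)) {
        if (deg[se[k]] == 0) next
        pv <- ppr_score(g, g$labels[se[k]], restart = ppr_restart,
                        tol = ppr_tol, max_iter = ppr_max_iter)
        sc[k, ] <- pv[dr]
      }
      sc
    },
    stop(sprintf("unknown baseline metric '%s'", metric))
  )
  dimnames(out) <- list(g$labels[se], g$labels[dr])
  out
}
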