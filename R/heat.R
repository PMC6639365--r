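#' Build the heat matrix of a weighted drug-drug graph
#'
#' The heat matrix H encodes conduction on the undirected weighted graph:
#' for an edge (j, i) with weight w_ji, the off-diagonal entry is
#' `H[i, j] = w_ji / d_j`, where d_j is the *weighted* degree of j (sum of
#' incident weights), and the diagonal is `H[i, i] = -tau_i`, with tau_i = 1
#' iff node i has at least one incident edge. Every column of a non-isolated
#' node therefore sums to zero, which makes the diffusion operators exactly
#' heat-conserving; isolated nodes get an all-zero row and column and keep
#' their heat.
#'
#' Interpreting d as the unweighted edge count is available via
#' `degree = "unweighted"` (columns then no longer sum to zero unless the
#' graph is unweighted).
#'
#' @param g A [similarity_graph()].
#' @param degree `"weighted"` (default) or `"unweighted"` degree convention.
#' @return Object of class `heat_matrix`: list with sparse `H` (n x n
#'   `dgCMatrix`) and `labels` in the graph's node order.
#' @export
build_heat_matrix <- function(g, degree = c("weighted", "unweighted")) {
  stopifnot(inherits(g, "similarity_graph"))
  degree <- match.arg(degree)
  n <- g$n
  e <- g$edges
  if (!nrow(e)) {
    warning("similarity graph has no edges; heat matrix is zero")
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n), dimnames = list(g$labels, g$labels))
    return(structure(list(H = H, labels = g$labels), class = "heat_matrix"))
  }
  d <- if (degree == "weighted") {
    unname(weighted_degree(g))
  } else {
    dd <- numeric(n)
    tb <- table(c(e$i, e$j))
    dd[as.integer(names(tb))] <- as.numeric(tb)
    dd
  }
  active <- which(d > 0)
  ii <- c(e$i, e$j, active)
  jj <- c(e$j, e$i, active)
  xx <- c(e$w / d[e$j], e$w / d[e$i], rep(-1, length(active)))
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(g$labels, g$labels))
  structure(list(H = H, labels = g$labels), class = "heat_matrix")
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf("heat_matrix: %d nodes, %d nonzero entries\n",
              length(x$labels), Matrix::nnzero(x$H)))
  invisible(x)
}

#' Exact heat diffusion via the matrix exponential kernel
#'
#' Computes `f(1) = expm(alpha * H) %*% f(0)`. Because every non-isolated
#' column of H sums to zero, the total heat `sum(f)` is conserved. The dense
#' matrix exponential costs O(n^3), so this operator is capped at small
#' graphs and serves as the reference for [diffuse_discrete()].
#'
#' @param Hm A `heat_matrix`.
#' @param f0 Nonnegative seed (initial heat) vector, length n.
#' @param alpha Thermal conductivity, > 0.
#' @param exact_cap Maximum n admitted (default 2000).
#' @return Numeric vector `f1` of diffused heat, named by node label.
#' @export
diffuse_exact <- function(Hm, f0, alpha = 1, exact_cap = 2000) {
  stopifnot(inherits(Hm, "heat_matrix"), alpha > 0)
  n <- length(Hm$labels)
  f0 <- as.numeric(f0)
  if (length(f0) != n) stop("f0 length does not match the graph")
  if (any(f0 < 0)) stop("f0 must be nonnegative")
  if (n > exact_cap) {
    stop(sprintf("graph has %d nodes > exact_cap = %d; use diffuse_discrete()",
                 n, exact_cap))
  }
  K <- Matrix::expm(alpha * Hm$H)
  f1 <- as.numeric(K %*% f0)
  names(f1) <- Hm$labels
  f1
}

#' Discrete approximation of heat diffusion
#'
#' Approximates the exponential kernel by `f(1) = (I + alpha/M * H)^M f(0)`,
#' applied as M successive sparse matrix-vector products (the dense power is
#' never formed), so one vector costs O(M |E|). The approximation error decays
#' as O(1/M). `alpha <= M` guarantees the propagation matrix
#' `I + (alpha/M) H` is entrywise nonnegative, hence `f1 >= 0`; total heat is
#' conserved up to floating-point roundoff.
#'
#' @param Hm A `heat_matrix`.
#' @param f0 Nonnegative seed vector (or a matrix whose columns are seed
#'   vectors, diffused simultaneously).
#' @param alpha Thermal conductivity, > 0 and <= M (default 1).
#' @param M Number of iterations (positive integer, default 30).
#' @return Numeric vector (or matrix, matching `f0`) of diffused heat.
#' @export
diffuse_discrete <- function(Hm, f0, alpha = 1, M = 30) {
  stopifnot(inherits(Hm, "heat_matrix"), alpha > 0)
  M <- as.integer(M)
  if (M < 1) stop("M must be a positive integer")
  if (alpha > M) {
    stop(sprintf("alpha = %g > M = %d: propagation matrix would have a negative diagonal",
                 alpha, M))
  }
  n <- length(Hm$labels)
  is_vec <- is.null(dim(f0))
  Fm <- if (is_vec) matrix(as.numeric(f0), ncol = 1) else as.matrix(f0)
  if (nrow(Fm) != n) stop("f0 length does not match the graph")
  if (any(Fm < 0)) stop("f0 must be nonnegative")
  step <- alpha / M
  for (k in seq_len(M)) {
    Fm <- Fm + step * as.matrix(Hm$H %*% Fm)
  }
  if (is_vec) {
    out <- Fm[, 1]
    names(out) <- Hm$labels
    out
  } else {
    rownames(Fm) <- Hm$labels
    Fm
  }
}

#' Diffuse every side effect's seed row over the drug similarity graph
#'
#' For each side effect i, takes row i of the completed matrix `Yhat` as the
#' seed vector f(0) and computes f(1) with [diffuse_discrete()]; the stacked
#' f(1) vectors form the prediction score matrix. Column labels of `Yhat`
#' must equal the similarity graph's node labels in the same order (use
#' [align_similarity_graph()] first).
#'
#' @param Yhat Nonnegative m x n matrix of seed weights (completed
#'   biadjacency, or the raw 0/1 matrix for diffusion-only scoring).
#' @param G A [similarity_graph()] over the same drugs, same order.
#' @param alpha Thermal conductivity (default 1).
#' @param M Iteration count (default 30).
#' @return m x n score matrix with `Yhat`'s dimnames and a `method` attribute
#'   recording the scorer and its parameters.
#' @export
propagate_all <- function(Yhat, G, alpha = 1, M = 30) {
  stopifnot(inherits(G, "similarity_graph"))
  Yhat <- as.matrix(Yhat)
  if (ncol(Yhat) != G$n ||
      (!is.null(colnames(Yhat)) && !identical(colnames(Yhat), G$labels))) {
    stop("Yhat columns are not aligned with the similarity graph's nodes")
  }
  Hm <- build_heat_matrix_quiet(G)
  scores <- t(diffuse_discrete(Hm, t(Yhat), alpha = alpha, M = M))
  dimnames(scores) <- dimnames(Yhat)
  attr(scores, "method") <- list(name = "heat_diffusion",
                                 alpha = alpha, M = M)
  scores
}

# build_heat_matrix without the edgeless warning (callers that accept it).
build_heat_matrix_quiet <- function(g, ...) {
  suppressWarnings(build_heat_matrix(g, ...))
}
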