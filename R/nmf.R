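#' Nonnegative matrix factorization of the biadjacency matrix
#'
#' Factorizes the m x n side-effect-drug matrix Y as Y ~ S D' with S (m x r)
#' and D (n x r) elementwise nonnegative, minimizing the squared Frobenius
#' error ||Y - SD'||_F^2 by Lee-Seung multiplicative updates. Zeros of Y enter
#' the objective as observed zeros (plain NMF over the full matrix, not a
#' masked factorization). The multiplicative updates make the objective
#' non-increasing, which the returned trace records per iteration.
#'
#' Factors are initialized from seeded uniform(0, 1) draws scaled by
#' `sqrt(mean(Y) / rank)` so the initial product has roughly the data's mean;
#' iteration stops at `max_iter` or when the relative objective decrease drops
#' below `rel_tol`.
#'
#' @param Y Numeric matrix (dense or sparse) with at least one nonzero entry;
#'   all entries must be nonnegative.
#' @param rank Factorization rank r, `1 <= r <= min(m, n)`.
#' @param max_iter Maximum number of update sweeps (default 500).
#' @param rel_tol Relative objective-decrease stopping tolerance (default 1e-6).
#' @param eps Small denominator guard for the multiplicative updates.
#' @param seed Integer RNG seed for the initialization; `NULL` uses the
#'   current RNG stream.
#' @return Object of class `nmf_factors`: list with nonnegative matrices `S`
#'   (m x r) and `D` (n x r), `rank`, `objective` (per-iteration trace of
#'   ||Y - SD'||_F^2, non-increasing), `iterations`, `converged`, `seed`.
#' @export
nmf_factorize <- function(Y, rank, max_iter = 500, rel_tol = 1e-6,
                          eps = 1e-9, seed = NULL) {
  Y <- as.matrix(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (any(Y < 0)) stop("Y must be nonnegative")
  if (all(Y == 0)) stop("cannot factorize an all-zero matrix")
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(m, n)) {
    stop(sprintf("rank must be in [1, %d], got %d", min(m, n), rank))
  }
  stopifnot(max_iter >= 1, rel_tol > 0, eps > 0)

  scale <- sqrt(mean(Y) / rank)
  init <- with_seed(seed, list(S = matrix(stats::runif(m * rank), m, rank),
                               D = matrix(stats::runif(n * rank), n, rank)))
  S <- init$S * scale
  D <- init$D * scale

  objective <- numeric(max_iter)
  obj_prev <- Inf
  it <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Lee-Seung updates for the Frobenius objective
    S <- S * (Y %*% D) / (S %*% crossprod(D) + eps)
    D <- D * (crossprod(Y, S)) / (D %*% crossprod(S) + eps)
    obj <- sum((Y - tcrossprod(S, D))^2)
    objective[it] <- obj
    if (is.finite(obj_prev) && obj_prev > 0 &&
        (obj_prev - obj) / obj_prev < rel_tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  structure(list(S = S, D = D, rank = rank,
                 objective = objective[seq_len(it)],
                 iterations = it, converged = converged, seed = seed,
                 dimnames = dimnames(Y)),
            class = "nmf_factors")
}

#' @export
print.nmf_factors <- function(x, ...) {
  cat(sprintf("nmf_factors: rank %d, %d x %d, %d iteration(s), objective %.6g%s\n",
              x$rank, nrow(x$S), nrow(x$D), x$iterations,
              x$objective[length(x$objective)],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Completed association matrix from fitted NMF factors
#'
#' Reconstructs the full matrix `Yhat = S D'`, replacing both the observed and
#' the unobserved cells of the 0/1 biadjacency matrix by real-valued
#' association scores. These rows are the seed (initial heat) vectors of the
#' diffusion step.
#'
#' @param fp An `nmf_factors` object from [nmf_factorize()].
#' @return Dense nonnegative matrix `Yhat` (m x n) carrying Y's dimnames.
#' @export
nmf_complete <- function(fp) {
  stopifnot(inherits(fp, "nmf_factors"))
  Yhat <- tcrossprod(fp$S, fp$D)
  dimnames(Yhat) <- fp$dimnames
  Yhat
}

#' Choose the NMF rank by held-out-link cross-validation
#'
#' Splits the observed links of `Y` into `inner_folds` groups. For each group
#' the matrix is refactorized with the group's links zeroed out, and the
#' reconstruction is scored by AUPR of recovering the held-out links against
#' an equal-count sample of never-observed cells. The rank with the highest
#' mean AUPR wins; ties go to the smallest rank.
#'
#' @param Y 0/1 biadjacency matrix.
#' @param candidate_ranks Integer vector of ranks to try (deduplicated; each
#'   must be `<= min(m, n)`).
#' @param inner_folds Number of inner folds (>= 2; default 3).
#' @param seed RNG seed controlling the fold assignment and negative sampling.
#' @param ... Passed to [nmf_factorize()] (`max_iter`, `rel_tol`, ...).
#' @return The chosen rank (integer).
#' @export
select_rank <- function(Y, candidate_ranks, inner_folds = 3, seed = 1, ...) {
  Y <- as.matrix(Y)
  ranks <- sort(unique(as.integer(candidate_ranks)))
  if (!length(ranks)) stop("no candidate ranks")
  if (any(ranks < 1 | ranks > min(dim(Y)))) {
    stop(sprintf("candidate ranks must be in [1, %d]", min(dim(Y))))
  }
  if (length(ranks) == 1) return(ranks)
  stopifnot(inner_folds >= 2)

  links <- observed_links(Y)
  n_links <- nrow(links)
  if (n_links < inner_folds) stop("fewer observed links than inner folds")
  fold_of <- with_seed(child_seed(seed, 1L), {
    sample(rep_len(seq_len(inner_folds), n_links))
  })
  zeros <- which(Y == 0)

  mean_aupr <- vapply(ranks, function(r) {
    fold_scores <- vapply(seq_len(inner_folds), function(f) {
      held <- links[fold_of == f, , drop = FALSE]
      Y_train <- Y
      Y_train[cbind(held$row, held$col)] <- 0
      if (all(Y_train == 0)) stop("inner fold leaves an all-zero training matrix")
      fp <- nmf_factorize(Y_train, rank = r, seed = child_seed(seed, 2L, f, r), ...)
      Yhat <- nmf_complete(fp)
      neg <- with_seed(child_seed(seed, 3L, f),
                       sample(zeros, min(length(zeros), nrow(held))))
      sc <- c(Yhat[cbind(held$row, held$col)], Yhat[neg])
      lab <- c(rep(1L, nrow(held)), rep(0L, length(neg)))
      aupr(sc, lab)$aupr
    }, numeric(1))
    mean(fold_scores)
  }, numeric(1))

  ranks[which.max(mean_aupr)]
}
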