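#' Fit the NMF-seeded heat-diffusion link predictor
#'
#' The model works in two stages. First the 0/1 side-effect-drug biadjacency
#' matrix Y is completed by nonnegative matrix factorization, Y ~ S D', so
#' every (side effect, drug) cell - observed or not - receives a nonnegative
#' association weight. Second, each side effect's completed row is used as the
#' initial heat vector f(0) of a diffusion process on the weighted drug-drug
#' similarity graph, f(1) = exp(alpha * H) f(0), approximated by M sparse
#' iterations of `(I + alpha/M * H)`. The diffused rows are the prediction
#' scores: drugs semantically close to a side effect's known drugs heat up
#' even when no link was observed.
#'
#' @param Y 0/1 biadjacency matrix (side effects x drugs) with dimnames,
#'   e.g. from [read_bipartite_edges()].
#' @param G Drug-drug [similarity_graph()]; it is reindexed to `colnames(Y)`
#'   automatically (drugs absent from `G` become isolated and keep their seed
#'   heat).
#' @param rank NMF rank r; alternatively `rank = NULL` selects it from
#'   `rank_candidates` by inner cross-validation ([select_rank()]).
#' @param alpha Thermal conductivity of the diffusion (default 1).
#' @param M Diffusion iteration count (default 30; requires `alpha <= M`).
#' @param rank_candidates Candidate ranks used when `rank` is `NULL`.
#' @param seed_known_only If `TRUE`, zero the completed matrix at cells with
#'   no observed link before diffusing, so only observed links carry seed
#'   heat (default `FALSE`: the full completed row is the seed).
#' @param max_iter,rel_tol,seed NMF controls, see [nmf_factorize()].
#' @return Object of class `heatlink`: list with the fitted `factors`
#'   (`nmf_factors`), completed matrix `Yhat`, diffused `scores`, aligned
#'   graph `G`, `alpha`, `M`, `rank`, and the `call`.
#' @seealso [predict.heatlink()], [cross_validate()], [generate_synthetic()]
#' @examples
#' toy <- make_toy_network()
#' fit <- heatlink(toy$Y, toy$G, rank = 2, seed = 42)
#' predict(fit, top_n = 3)
#' @export
heatlink <- function(Y, G, rank, alpha = 1, M = 30,
                     rank_candidates = 1:6, seed_known_only = FALSE,
                     max_iter = 500, rel_tol = 1e-6, seed = 1) {
  stopifnot(inherits(G, "similarity_graph"))
  if (is.null(rownames(Y)) || is.null(colnames(Y))) stop("Y must carry dimnames")
  G <- align_similarity_graph(G, colnames(Y))
  if (missing(rank) || is.null(rank)) {
    rank <- select_rank(Y, rank_candidates, seed = seed,
                        max_iter = max_iter, rel_tol = rel_tol)
  }
  fp <- nmf_factorize(Y, rank = rank, max_iter = max_iter,
                      rel_tol = rel_tol, seed = seed)
  Yhat <- nmf_complete(fp)
  seeds <- if (seed_known_only) Yhat * (as.matrix(Y) > 0) else Yhat
  scores <- propagate_all(seeds, G, alpha = alpha, M = M)
  attr(scores, "method") <- list(name = "hd_nmf", alpha = alpha, M = M,
                                 rank = rank, seed_known_only = seed_known_only)
  structure(list(factors = fp, Yhat = Yhat, scores = scores, G = G,
                 Y = Y, alpha = alpha, M = M, rank = rank,
                 seed_known_only = seed_known_only, call = match.call()),
            class = "heatlink")
}

#' @export
print.heatlink <- function(x, ...) {
  cat("NMF-seeded heat-diffusion link predictor\n")
  cat(sprintf("  %d side effects x %d drugs, %d observed links\n",
              nrow(x$Y), ncol(x$Y), sum(as.matrix(x$Y) != 0)))
  cat(sprintf("  NMF rank %d (%d iterations, objective %.4g)\n",
              x$rank, x$factors$iterations,
              x$factors$objective[length(x$factors$objective)]))
  cat(sprintf("  diffusion: alpha = %g, M = %d on %d similarity edges\n",
              x$alpha, x$M, nrow(x$G$edges)))
  invisible(x)
}

#' @export
summary.heatlink <- function(object, ...) {
  Y <- as.matrix(object$Y)
  obs <- Y != 0
  out <- list(dims = dim(Y), n_links = sum(obs),
              rank = object$rank, alpha = object$alpha, M = object$M,
              objective = object$factors$objective[length(object$factors$objective)],
              iterations = object$factors$iterations,
              converged = object$factors$converged,
              reconstruction_rel_error =
                sqrt(sum((Y - object$Yhat)^2) / sum(Y^2)),
              heat_in = rowSums(object$Yhat),
              heat_out = rowSums(object$scores),
              score_range_new = range(object$scores[!obs]))
  class(out) <- "summary.heatlink"
  out
}

#' @export
print.summary.heatlink <- function(x, ...) {
  cat(sprintf("heatlink fit: %d x %d, %d links, rank %d, alpha = %g, M = %d\n",
              x$dims[1], x$dims[2], x$n_links, x$rank, x$alpha, x$M))
  cat(sprintf("  NMF objective %.4g after %d iteration(s)%s; relative fit error %.3g\n",
              x$objective, x$iterations,
              if (x$converged) " (converged)" else "",
              x$reconstruction_rel_error))
  cat(sprintf("  heat conservation: max |in - out| = %.3g\n",
              max(abs(x$heat_in - x$heat_out))))
  cat(sprintf("  scores of previously unlinked pairs in [%.4g, %.4g]\n",
              x$score_range_new[1], x$score_range_new[2]))
  invisible(x)
}

#' Ranked link predictions from a fitted model
#'
#' @param object A [heatlink()] fit.
#' @param side_effects Optional subset of side-effect labels (default: all).
#' @param top_n Number of drugs reported per side effect (default 10).
#' @param new_only If `TRUE` (default), only pairs without an observed link
#'   are ranked - the model's actual predictions; `FALSE` ranks all drugs.
#' @param ... Unused.
#' @return Data frame with `side_effect`, `drug`, `score`, `rank`, ordered by
#'   side effect then rank; ties broken by drug label.
#' @export
predict.heatlink <- function(object, side_effects = NULL, top_n = 10,
                             new_only = TRUE, ...) {
  rows <- if (is.null(side_effects)) rownames(object$Y) else as.character(side_effects)
  miss <- setdiff(rows, rownames(object$Y))
  if (length(miss)) stop("unknown side effect(s): ", paste(miss, collapse = ", "))
  Y <- as.matrix(object$Y)
  out <- lapply(rows, function(se) {
    sc <- object$scores[se, ]
    if (new_only) sc <- sc[Y[se, ] == 0]
    if (!length(sc)) return(NULL)
    k <- min(top_n, length(sc))
    ord <- order(-sc, names(sc))[seq_len(k)]
    data.frame(side_effect = se, drug = names(sc)[ord],
               score = unname(sc[ord]), rank = seq_len(k))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
fitted.heatlink <- function(object, ...) object$scores

#' @export
coef.heatlink <- function(object, ...) {
  list(S = object$factors$S, D = object$factors$D)
}

#' @export
residuals.heatlink <- function(object, ...) {
  as.matrix(object$Y) - object$Yhat
}
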