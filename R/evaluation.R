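#' Stratified k-fold split of observed links
#'
#' Partitions the observed (side effect, drug) links into `k` disjoint folds,
#' stratified per side-effect row: each row's links are spread as evenly as
#' possible over the folds (per-row fold sizes differ by at most 1), so every
#' training matrix retains about (k-1)/k of each row's links. Deterministic
#' given the seed.
#'
#' @param Y 0/1 biadjacency matrix; every side effect must have >= 1 link.
#' @param k Fold count (>= 2, <= total links).
#' @param seed Integer RNG seed.
#' @return Object of class `fold_split`: list with `assignments` (data frame
#'   `row`, `col`, `fold`), `k`, `seed`.
#' @export
split_folds <- function(Y, k, seed = 1) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  links <- observed_links(Y)
  if (nrow(links) < k) stop("more folds than observed links")
  row_links <- Matrix::rowSums(Y != 0)
  if (any(row_links == 0)) stop("every side effect must have at least one link")
  fold <- integer(nrow(links))
  with_seed(seed, {
    # per-row round robin continuing a global pointer: per-row AND overall
    # fold sizes both differ by at most 1
    ptr <- sample.int(k, 1) - 1L
    for (i in sample(unique(links$row))) {
      idx <- which(links$row == i)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- (ptr + length(idx)) %% k
    }
  })
  structure(list(assignments = data.frame(row = links$row, col = links$col,
                                          fold = fold),
                 k = k, seed = seed),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: %d links in %d folds (sizes %s)\n",
              nrow(x$assignments), x$k,
              paste(tabulate(x$assignments$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Precision-recall curve and its area
#'
#' Ranks by descending score; tied scores form a single threshold step, so
#' the curve has one (recall, precision) point per distinct score value. The
#' curve is anchored at (recall 0, precision 1) and the area is computed by
#' the trapezoidal rule over the points.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels 0/1 (or logical) vector of the same length; at least one
#'   positive and one negative required.
#' @return Object of class `pr_curve`: list with `recall`, `precision`
#'   (including the anchor) and scalar `aupr` in [0, 1].
#' @export
aupr <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("non-finite scores")
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) {
    stop("aupr needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # last index of each distinct-score tie group
  step_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[step_end]
  fp <- cumsum(1 - y)[step_end]
  recall <- tp / P
  precision <- tp / (tp + fp)
  r <- c(0, recall)
  p <- c(1, precision)
  area <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  structure(list(recall = r, precision = p, aupr = area), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d points, AUPR = %.4f\n", length(x$recall), x$aupr))
  invisible(x)
}

#' Paired t-test on per-fold AUPR vectors
#'
#' Two-sided paired Student t-test with k - 1 degrees of freedom on the
#' per-fold differences, under the null of equal performance.
#'
#' @param a,b Numeric vectors of per-fold AUPR values, equal length k >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps * max(1, max(abs(d)))) {
    stop("degenerate t-test: per-fold differences have zero variance")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

# ---- scorer registry -------------------------------------------------------

#' Built-in scorer names accepted by [cross_validate()] and friends
#' @return Character vector of method names.
#' @export
available_methods <- function() {
  c("hd_nmf", "nmf", "diffusion", "common_neighbors", "jaccard",
    "adamic_adar", "resource_allocation", "katz", "ppr", "random")
}

# Compute a full m x n score matrix for one method on a training matrix.
score_matrix_for <- function(method, Y_train, G, params, seed) {
  if (all(Y_train == 0)) stop("training matrix is all zero; method untrainable")
  switch(method,
    hd_nmf = {
      fp <- nmf_factorize(Y_train, rank = params$rank, max_iter = params$max_iter,
                          rel_tol = params$rel_tol, seed = seed)
      Yhat <- nmf_complete(fp)
      if (isTRUE(params$seed_known_only)) Yhat <- Yhat * (as.matrix(Y_train) > 0)
      propagate_all(Yhat, G, alpha = params$alpha, M = params$M)
    },
    nmf = {
      fp <- nmf_factorize(Y_train, rank = params$rank, max_iter = params$max_iter,
                          rel_tol = params$rel_tol, seed = seed)
      nmf_complete(fp)
    },
    diffusion = propagate_all(as.matrix(Y_train), G,
                              alpha = params$alpha, M = params$M),
    random = {
      m <- nrow(Y_train); n <- ncol(Y_train)
      sc <- matrix(with_seed(seed, stats::runif(m * n)), m, n)
      dimnames(sc) <- dimnames(Y_train)
      sc
    },
    {
      g <- combined_graph(Y_train, G)
      baseline_score_matrix(g, method,
                            katz_beta = params$katz_beta,
                            katz_lmax = params$katz_lmax,
                            ppr_restart = params$ppr_restart,
                            ppr_tol = params$ppr_tol,
                            ppr_max_iter = params$ppr_max_iter)
    }
  )
}

default_eval_params <- function(...) {
  p <- list(rank = 3, alpha = 1, M = 30, max_iter = 500, rel_tol = 1e-6,
            seed_known_only = FALSE,
            katz_beta = 0.005, katz_lmax = 4,
            ppr_restart = 0.15, ppr_tol = 1e-8, ppr_max_iter = 1000)
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' k-fold cross-validated AUPR comparison of link-prediction methods
#'
#' For each fold, the fold's links are removed from `Y` to form the training
#' matrix; every method is trained/scored on it. The candidate set is, per
#' side effect, all drugs without a training link; the fold's held-out links
#' are the positives and never-observed pairs the negatives. Scores are pooled
#' over all candidates into one AUPR per fold per method.
#'
#' @param Y 0/1 biadjacency matrix.
#' @param G [similarity_graph()] aligned to `colnames(Y)`.
#' @param methods Character vector of method names (see
#'   [available_methods()]). `hd_nmf` is NMF completion followed by heat
#'   diffusion; `nmf` and `diffusion` are the two components run alone.
#' @param split A [split_folds()] result for `Y`.
#' @param ... Method parameters overriding the defaults: `rank`, `alpha`, `M`,
#'   `max_iter`, `rel_tol`, `katz_beta`, `katz_lmax`, `ppr_restart`,
#'   `ppr_tol`, `ppr_max_iter`, `seed_known_only`.
#' @return Object of class `cv_report`: list with `aupr` (k x methods
#'   matrix of per-fold AUPR), `mean`, `sd`, `methods`, `k`, `params`.
#' @export
cross_validate <- function(Y, G, methods, split, ...) {
  stopifnot(inherits(split, "fold_split"))
  methods <- as.character(methods)
  bad <- setdiff(unique(methods), available_methods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  params <- default_eval_params(...)
  Yd <- as.matrix(Y)
  k <- split$k
  res <- matrix(NA_real_, k, length(methods),
                dimnames = list(NULL, make.unique(methods)))
  for (f in seq_len(k)) {
    held <- split$assignments[split$assignments$fold == f, , drop = FALSE]
    Y_train <- Yd
    Y_train[cbind(held$row, held$col)] <- 0
    if (all(Y_train == 0)) stop(sprintf("fold %d leaves an all-zero training matrix", f))
    cand <- which(Y_train == 0)
    lab <- as.integer(Yd[cand] != 0)
    for (j in seq_along(methods)) {
      sc <- try(score_matrix_for(methods[j], Y_train, G, params,
                                 seed = child_seed(split$seed, f,
                                                   match(methods[j], available_methods()))),
                silent = TRUE)
      if (inherits(sc, "try-error")) {
        stop(sprintf("method '%s' failed on fold %d: %s", methods[j], f,
                     attr(sc, "condition")$message))
      }
      res[f, j] <- aupr(sc[cand], lab)$aupr
    }
  }
  structure(list(aupr = res,
                 mean = colMeans(res), sd = apply(res, 2, stats::sd),
                 methods = methods, k = k, params = params,
                 prevalence = mean(Yd != 0)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validated AUPR:\n", x$k))
  tab <- data.frame(method = colnames(x$aupr),
                    mean_aupr = round(x$mean, digits),
                    sd = round(x$sd, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise t-tests of a cross-validation report against a reference method
#'
#' @param report A [cross_validate()] result.
#' @param reference Method (column name) every other method is compared to.
#' @return Data frame with columns `method`, `t`, `p`.
#' @export
method_ttests <- function(report, reference = "hd_nmf") {
  stopifnot(inherits(report, "cv_report"))
  cols <- colnames(report$aupr)
  if (!reference %in% cols) stop("reference method not in report")
  others <- setdiff(cols, reference)
  out <- lapply(others, function(mth) {
    tt <- paired_ttest(report$aupr[, reference], report$aupr[, mth])
    data.frame(method = mth, t = tt$t, p = tt$p)
  })
  do.call(rbind, out)
}

#' Degree-preserving randomization of a similarity graph
#'
#' Applies double-edge swaps: two edges (a, b) and (c, d) are rewired to
#' (a, d) and (c, b) when this creates neither a self-loop nor a duplicate
#' edge. Each surviving edge keeps its original weight, so the unweighted
#' degree multiset is exactly preserved while the topology is shuffled.
#' Graphs with fewer than 2 edges are returned unchanged.
#'
#' @param g A [similarity_graph()].
#' @param seed Integer RNG seed.
#' @param n_swaps Number of attempted swaps (default `10 * |E|`).
#' @return A randomized `similarity_graph` on the same nodes.
#' @export
degree_preserving_randomize <- function(g, seed = 1, n_swaps = 10 * nrow(g$edges)) {
  stopifnot(inherits(g, "similarity_graph"))
  ne <- nrow(g$edges)
  if (ne < 2) return(g)
  ei <- g$edges$i; ej <- g$edges$j; ew <- g$edges$w
  key <- function(a, b) ifelse(a < b, a * (g$n + 1) + b, b * (g$n + 1) + a)
  present <- new.env(hash = TRUE, size = ne * 2)
  for (k in seq_len(ne)) assign(as.character(key(ei[k], ej[k])), TRUE, envir = present)
  with_seed(seed, {
    for (s in seq_len(n_swaps)) {
      pick <- sample.int(ne, 2)
      a <- ei[pick[1]]; b <- ej[pick[1]]
      c_ <- ei[pick[2]]; d_ <- ej[pick[2]]
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d_; d_ <- tmp }
      # proposed: (a, d_), (c_, b)
      if (a == d_ || c_ == b) next
      k1 <- as.character(key(a, d_)); k2 <- as.character(key(c_, b))
      if (k1 == k2 || exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE)) next
      rm(list = c(as.character(key(a, b)), as.character(key(c_, d_))),
         envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      ei[pick[1]] <- min(a, d_); ej[pick[1]] <- max(a, d_)
      ei[pick[2]] <- min(c_, b); ej[pick[2]] <- max(c_, b)
    }
  })
  similarity_graph(g$labels,
                   data.frame(from = g$labels[ei], to = g$labels[ej], weight = ew),
                   quiet = TRUE)
}

#' Permutation test of diffusion scores against degree-preserving nulls
#'
#' Scores each test pair with NMF-seeded heat diffusion on the real similarity
#' graph, then `N` times randomizes the graph (degree-preserving), rediffuses
#' the *same* seed vectors, and counts per pair the randomized runs whose
#' score strictly exceeds the actual one (Omega). The p-value is Omega / N.
#'
#' @param Y_train 0/1 biadjacency training matrix.
#' @param G [similarity_graph()] aligned to `colnames(Y_train)`.
#' @param test_pairs Data frame with integer columns `row`, `col` indexing
#'   the pairs to test.
#' @param N Number of randomizations (>= 1; default 1000).
#' @param seed Integer RNG seed.
#' @param ... Method parameters as in [cross_validate()] (`rank`, `alpha`,
#'   `M`, ...).
#' @return Object of class `perm_test`: data frame with `side_effect`,
#'   `drug`, `actual`, `omega`, `p`, plus attributes `N` and `seed`.
#' @export
permutation_pvalues <- function(Y_train, G, test_pairs, N = 1000, seed = 1, ...) {
  stopifnot(N >= 1, all(c("row", "col") %in% names(test_pairs)))
  params <- default_eval_params(...)
  Yd <- as.matrix(Y_train)
  fp <- nmf_factorize(Yd, rank = params$rank, max_iter = params$max_iter,
                      rel_tol = params$rel_tol, seed = child_seed(seed, 0L))
  Yhat <- nmf_complete(fp)
  rows <- sort(unique(test_pairs$row))
  seeds <- Yhat[rows, , drop = FALSE]
  idx <- cbind(match(test_pairs$row, rows), test_pairs$col)

  actual_full <- propagate_all(seeds, G, alpha = params$alpha, M = params$M)
  actual <- actual_full[idx]
  omega <- integer(nrow(test_pairs))
  for (t in seq_len(N)) {
    Gr <- degree_preserving_randomize(G, seed = child_seed(seed, t))
    rand_scores <- propagate_all(seeds, Gr, alpha = params$alpha, M = params$M)[idx]
    omega <- omega + (rand_scores > actual)
  }
  out <- data.frame(side_effect = rownames(Yd)[test_pairs$row],
                    drug = colnames(Yd)[test_pairs$col],
                    actual = actual, omega = omega, p = omega / N)
  attr(out, "N") <- N
  attr(out, "seed") <- seed
  class(out) <- c("perm_test", "data.frame")
  out
}

#' Mean AUPR as a function of the training fraction
#'
#' For each fraction f, keeps a uniformly random f of the observed links for
#' training and tests recovery of the rest (negatives: never-observed pairs),
#' scoring with NMF-seeded heat diffusion; reports the mean AUPR over
#' `repeats` re-draws.
#'
#' @param Y 0/1 biadjacency matrix.
#' @param G [similarity_graph()] aligned to `colnames(Y)`.
#' @param fractions Numeric vector of training fractions in (0, 1).
#' @param repeats Redraws per fraction (default 3).
#' @param seed Integer RNG seed.
#' @param method Scorer to evaluate (default `"hd_nmf"`).
#' @param ... Method parameters as in [cross_validate()].
#' @return Data frame with `fraction`, `mean_aupr`, `sd_aupr`.
#' @export
training_fraction_sweep <- function(Y, G, fractions, repeats = 3, seed = 1,
                                    method = "hd_nmf", ...) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  params <- default_eval_params(...)
  Yd <- as.matrix(Y)
  links <- observed_links(Yd)
  n_links <- nrow(links)
  out <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    n_keep <- round(f * n_links)
    if (n_keep < 1) stop(sprintf("fraction %g leaves zero training links", f))
    if (n_keep >= n_links) stop(sprintf("fraction %g leaves zero test links", f))
    reps <- vapply(seq_len(repeats), function(r) {
      keep <- with_seed(child_seed(seed, fi, r), sample.int(n_links, n_keep))
      Y_train <- Yd
      Y_train[cbind(links$row[-keep], links$col[-keep])] <- 0
      sc <- score_matrix_for(method, Y_train, G, params,
                             seed = child_seed(seed, fi, r, 1L))
      cand <- which(Y_train == 0)
      aupr(sc[cand], as.integer(Yd[cand] != 0))$aupr
    }, numeric(1))
    data.frame(fraction = f, mean_aupr = mean(reps), sd_aupr = stats::sd(reps))
  })
  do.call(rbind, out)
}
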