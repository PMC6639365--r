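#' Generate a planted latent-factor benchmark dataset
#'
#' Draws nonnegative latent factors `S*` (m x r) and `D*` (n x r) from seeded
#' exponential(1) distributions and builds (i) the latent score matrix
#' `Y_true = S* D*'`, (ii) an observed 0/1 biadjacency matrix with exactly
#' `floor(link_density * m * n)` positives - each side effect's single
#' top-scoring cell first, then the globally top-scoring remaining cells - so
#' the density is exact, every row is covered and selection is deterministic;
#' a held-out fraction of positives is removed uniformly for benchmarking;
#' and (iii) a drug-drug similarity graph from the
#' cosine similarities of the rows of `D*`, perturbed by symmetric Gaussian
#' noise of sd `sim_noise` (non-positive weights dropped). Because the
#' similarity graph derives from the same latent drug factors that generate
#' links, similar drugs share side effects by construction - the structural
#' assumption the diffusion method exploits.
#'
#' One uniformly chosen link per side effect is protected from hold-out so
#' every row of the observed matrix keeps at least one link.
#'
#' @param m,n Numbers of side effects and drugs.
#' @param r_true Planted rank (`<= min(m, n)`).
#' @param link_density Fraction of the m x n cells that are positive links,
#'   in (0, 1).
#' @param sim_noise Sd of the Gaussian perturbation of the cosine
#'   similarities (>= 0; 0 gives the noiseless graph).
#' @param held_out_frac Fraction of positives held out of the observed
#'   matrix (default 0.1).
#' @param seed Integer RNG seed; the whole dataset is deterministic given it.
#' @return Object of class `synthetic_dataset`: list with `Y_true`, `Y_obs`
#'   (sparse 0/1), `held_out` (data frame `row`, `col`), `G`
#'   ([similarity_graph()]), and `spec` (the generating parameters).
#' @export
generate_synthetic <- function(m = 50, n = 40, r_true = 3, link_density = 0.12,
                               sim_noise = 0, held_out_frac = 0.1, seed = 1) {
  stopifnot(r_true >= 1, r_true <= min(m, n),
            link_density > 0, link_density < 1,
            sim_noise >= 0, held_out_frac >= 0, held_out_frac < 1)
  n_pos <- floor(link_density * m * n)
  if (n_pos < m) stop("link density too low: fewer positives than side effects")
  row_labels <- sprintf("SE%03d", seq_len(m))
  col_labels <- sprintf("D%03d", seq_len(n))

  for (attempt in seq_len(10)) {
    at_seed <- child_seed(seed, attempt)
    dat <- with_seed(at_seed, {
      S_true <- matrix(stats::rexp(m * r_true), m, r_true)
      D_true <- matrix(stats::rexp(n * r_true), n, r_true)
      Y_true <- tcrossprod(S_true, D_true)
      # every row's best cell is a positive; the rest of the budget goes to
      # the globally top-scoring remaining cells
      row_best <- seq_len(m) + m * (max.col(Y_true, ties.method = "first") - 1L)
      fill <- setdiff(order(Y_true, decreasing = TRUE), row_best)
      pos <- c(row_best, fill[seq_len(n_pos - m)])
      pos_rc <- arrayInd(pos, dim(Y_true))
      if (length(unique(pos_rc[, 1])) < m) {
        NULL  # unreachable with per-row coverage; kept as a guard
      } else {
        # protect one random link per row, hold out from the rest
        n_held <- round(held_out_frac * n_pos)
        protected <- vapply(split(seq_len(n_pos), pos_rc[, 1]),
                            function(ix) ix[sample.int(length(ix), 1)],
                            integer(1))
        eligible <- setdiff(seq_len(n_pos), protected)
        held <- sort(eligible[sample.int(length(eligible),
                                         min(n_held, length(eligible)))])
        obs <- setdiff(seq_len(n_pos), held)
        C <- tcrossprod(D_true / sqrt(rowSums(D_true^2)))
        if (sim_noise > 0) {
          E <- matrix(stats::rnorm(n * n, 0, sim_noise), n, n)
          C <- C + (E + t(E)) / 2
        }
        ut <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
        list(S_true = S_true, D_true = D_true, Y_true = Y_true,
             pos_rc = pos_rc, obs = obs, held = held, C = C, ut = ut)
      }
    })
    if (!is.null(dat)) break
    if (attempt == 10) stop("link density too low: a side effect had no positive after 10 attempts")
  }

  dimnames(dat$Y_true) <- list(row_labels, col_labels)
  Y_obs <- Matrix::sparseMatrix(i = dat$pos_rc[dat$obs, 1],
                                j = dat$pos_rc[dat$obs, 2], x = 1,
                                dims = c(m, n),
                                dimnames = list(row_labels, col_labels))
  G <- similarity_graph(col_labels,
                        data.frame(from = col_labels[dat$ut[, 1]],
                                   to = col_labels[dat$ut[, 2]],
                                   weight = dat$C[dat$ut]),
                        quiet = TRUE)
  structure(list(Y_true = dat$Y_true, Y_obs = Y_obs,
                 held_out = data.frame(row = dat$pos_rc[dat$held, 1],
                                       col = dat$pos_rc[dat$held, 2]),
                 G = G,
                 S_true = dat$S_true, D_true = dat$D_true,
                 spec = list(m = m, n = n, r_true = r_true,
                             link_density = link_density,
                             sim_noise = sim_noise,
                             held_out_frac = held_out_frac, seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d side effects x %d drugs, rank %d, ",
                     "%d observed + %d held-out links, %d similarity edges\n"),
              x$spec$m, x$spec$n, x$spec$r_true,
              Matrix::nnzero(x$Y_obs), nrow(x$held_out), nrow(x$G$edges)))
  invisible(x)
}

#' Small fixed toy network for end-to-end smoke tests
#'
#' Loads the 3-side-effect x 6-drug toy shipped in `inst/extdata/`: a sparse
#' bipartite pattern plus a connected weighted 6-node drug similarity graph.
#' Weights are this package's own choices, documented in the fixture files.
#'
#' @return List with `Y` (sparse 0/1 biadjacency) and `G`
#'   ([similarity_graph()] aligned to `colnames(Y)`).
#' @export
make_toy_network <- function() {
  bi <- system.file("extdata", "toy_bipartite.tsv", package = "heatlink",
                    mustWork = TRUE)
  si <- system.file("extdata", "toy_similarity.tsv", package = "heatlink",
                    mustWork = TRUE)
  Y <- read_bipartite_edges(bi)
  G <- align_similarity_graph(read_similarity_edges(si, quiet = TRUE),
                              colnames(Y))
  list(Y = Y, G = G)
}

#' Write a dataset's graphs in the package's TSV exchange formats
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`bipartite`, `similarity`,
#'   `held_out`).
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  links <- observed_links(dataset$Y_obs)
  bp <- file.path(dir, "bipartite.tsv")
  writeLines(sprintf("%s\t%s", rownames(dataset$Y_obs)[links$row],
                     colnames(dataset$Y_obs)[links$col]), bp)
  sp <- file.path(dir, "similarity.tsv")
  e <- dataset$G$edges
  writeLines(sprintf("%s\t%s\t%.17g", dataset$G$labels[e$i],
                     dataset$G$labels[e$j], e$w), sp)
  hp <- file.path(dir, "held_out.tsv")
  writeLines(sprintf("%s\t%s", rownames(dataset$Y_obs)[dataset$held_out$row],
                     colnames(dataset$Y_obs)[dataset$held_out$col]), hp)
  invisible(c(bipartite = bp, similarity = sp, held_out = hp))
}
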