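#' Construct an undirected weighted drug-drug similarity graph
#'
#' The graph stores node labels plus an undirected edge list with strictly
#' positive weights. Self-loops and edges with weight <= 0 are dropped (with a
#' message reporting the counts); duplicate edges with equal weight are merged,
#' while duplicates with conflicting weights raise an error. The weighted
#' degree of a node is the sum of the weights of its incident edges; a node is
#' "active" (tau = 1) iff its weighted degree is positive.
#'
#' @param labels Character vector of unique node (drug) labels.
#' @param edges Data frame with columns `from`, `to` (labels present in
#'   `labels`) and `weight` (finite numeric). May have zero rows.
#' @param quiet Suppress the dropped-edge message.
#' @return An object of class `similarity_graph`: a list with `labels`,
#'   `edges` (data frame of integer endpoints `i < j` and weight `w`) and `n`.
#' @export
similarity_graph <- function(labels,
                             edges = data.frame(from = character(),
                                                to = character(),
                                                weight = numeric()),
                             quiet = FALSE) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate node labels in similarity graph")
  n <- length(labels)
  i <- match(as.character(edges$from), labels)
  j <- match(as.character(edges$to), labels)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$from[is.na(i)], edges$to[is.na(j)]))
    stop("edge endpoints not in node labels: ", paste(bad, collapse = ", "))
  }
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w))) stop("non-finite edge weights")

  loops <- i == j
  nonpos <- !loops & w <= 0
  keep <- !loops & !nonpos
  if (!quiet && any(loops | nonpos)) {
    message(sprintf("similarity_graph: dropped %d self-loop(s) and %d non-positive edge(s)",
                    sum(loops), sum(nonpos)))
  }
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp

  key <- paste(i, j)
  if (anyDuplicated(key)) {
    grp <- split(w, key)
    rng <- vapply(grp, function(x) diff(range(x)), numeric(1))
    if (any(rng > 1e-9 * pmax(1, vapply(grp, max, numeric(1))))) {
      bad <- names(grp)[rng > 1e-9]
      idx <- as.integer(strsplit(bad[1], " ")[[1]])
      stop(sprintf("conflicting duplicate weights for edge %s--%s",
                   labels[idx[1]], labels[idx[2]]))
    }
    first <- !duplicated(key)
    i <- i[first]; j <- j[first]; w <- w[first]
  }

  structure(list(labels = labels,
                 edges = data.frame(i = i, j = j, w = w),
                 n = n),
            class = "similarity_graph")
}

#' Weighted degrees of a similarity graph
#'
#' @param g A `similarity_graph`.
#' @return Named numeric vector: per node, the sum of incident edge weights.
#' @export
weighted_degree <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  d <- numeric(g$n)
  if (nrow(g$edges)) {
    agg <- rowsum(c(g$edges$w, g$edges$w), c(g$edges$i, g$edges$j))
    d[as.integer(rownames(agg))] <- agg[, 1]
  }
  names(d) <- g$labels
  d
}

#' @export
print.similarity_graph <- function(x, ...) {
  d <- weighted_degree(x)
  cat(sprintf("similarity_graph: %d nodes, %d edges (%d isolated)\n",
              x$n, nrow(x$edges), sum(d == 0)))
  invisible(x)
}

#' Read a drug-drug similarity graph from a weighted edge list
#'
#' Each non-comment line must hold `drug <TAB> drug <TAB> weight`. Both
#' orientations of a pair may appear if their weights agree; conflicting
#' weights raise an error. Non-positive weights and self-loops are dropped
#' with a message. Node order is first-appearance order.
#'
#' @param path Path to the TSV file; `#` lines are comments.
#' @param quiet Suppress the dropped-edge message.
#' @return A [similarity_graph()].
#' @export
read_similarity_edges <- function(path, quiet = FALSE) {
  parsed <- read_delim_lines(path)
  if (!length(parsed$fields)) {
    return(similarity_graph(character(0), quiet = quiet))
  }
  nf <- lengths(parsed$fields)
  if (any(nf != 3)) {
    k <- which(nf != 3)[1]
    stop_bad_line(path, parsed$lineno[k], parsed$raw[k], "3 fields: drug, drug, weight")
  }
  from <- vapply(parsed$fields, `[`, character(1), 1)
  to <- vapply(parsed$fields, `[`, character(1), 2)
  w <- suppressWarnings(as.numeric(vapply(parsed$fields, `[`, character(1), 3)))
  if (anyNA(w)) {
    k <- which(is.na(w))[1]
    stop_bad_line(path, parsed$lineno[k], parsed$raw[k], "numeric weight")
  }
  labels <- unique(c(rbind(from, to)))
  similarity_graph(labels, data.frame(from = from, to = to, weight = w),
                   quiet = quiet)
}

#' Reindex a similarity graph to a prescribed drug order
#'
#' Aligns the node order of `g` to `labels` (typically the column labels of
#' the bipartite matrix) so diffusion operates index-aligned with the
#' biadjacency columns. Drugs absent from `g` become isolated nodes; nodes of
#' `g` absent from `labels` are dropped together with their edges.
#'
#' @param g A `similarity_graph`.
#' @param labels Character vector of target drug labels (unique).
#' @return A `similarity_graph` over exactly `labels`, in that order.
#' @export
align_similarity_graph <- function(g, labels) {
  stopifnot(inherits(g, "similarity_graph"))
  labels <- as.character(labels)
  e <- g$edges
  keep <- g$labels[e$i] %in% labels & g$labels[e$j] %in% labels
  similarity_graph(labels,
                   data.frame(from = g$labels[e$i[keep]],
                              to = g$labels[e$j[keep]],
                              weight = e$w[keep]),
                   quiet = TRUE)
}
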