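#' Build a side-effect x drug biadjacency matrix from label pairs
#'
#' @param side_effects,drugs Character vectors of equal length giving observed
#'   (side effect, drug) links. Duplicated pairs collapse to a single entry.
#' @param row_labels,col_labels Optional label orders; default is
#'   first-appearance order in the input.
#' @return A sparse 0/1 `dgCMatrix` with side effects as rows and drugs as
#'   columns; observed links are exactly 1.
#' @export
bipartite_adjacency <- function(side_effects, drugs,
                                row_labels = unique(side_effects),
                                col_labels = unique(drugs)) {
  side_effects <- as.character(side_effects)
  drugs <- as.character(drugs)
  stopifnot(length(side_effects) == length(drugs))
  if (!length(side_effects)) stop("empty bipartite graph")
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("duplicate labels in bipartite graph")
  }
  i <- match(side_effects, row_labels)
  j <- match(drugs, col_labels)
  if (anyNA(i) || anyNA(j)) stop("link endpoints missing from label registries")
  dup <- duplicated(cbind(i, j))
  Matrix::sparseMatrix(i = i[!dup], j = j[!dup], x = 1,
                       dims = c(length(row_labels), length(col_labels)),
                       dimnames = list(row_labels, col_labels))
}

#' Read a side-effect-drug bipartite edge list
#'
#' Each non-comment line must hold `side_effect <TAB> drug`. Duplicate pairs
#' collapse silently; label order is first-appearance order.
#'
#' @param path Path to the TSV file; `#` lines are comments.
#' @return A sparse 0/1 biadjacency matrix (side effects x drugs).
#' @export
read_bipartite_edges <- function(path) {
  parsed <- read_delim_lines(path)
  if (!length(parsed$fields)) stop("empty bipartite graph")
  nf <- lengths(parsed$fields)
  if (any(nf != 2)) {
    k <- which(nf != 2)[1]
    stop_bad_line(path, parsed$lineno[k], parsed$raw[k], "2 fields: side_effect, drug")
  }
  se <- vapply(parsed$fields, `[`, character(1), 1)
  dr <- vapply(parsed$fields, `[`, character(1), 2)
  bipartite_adjacency(se, dr)
}

# Observed (row, col) index pairs of a 0/1 biadjacency matrix (sparse or dense).
observed_links <- function(Y) {
  if (methods::is(Y, "Matrix")) {
    Tm <- methods::as(methods::as(methods::as(Y, "dMatrix"), "generalMatrix"),
                      "TsparseMatrix")
    keep <- Tm@x != 0
    out <- data.frame(row = Tm@i[keep] + 1L, col = Tm@j[keep] + 1L)
    out[order(out$col, out$row), , drop = FALSE]
  } else {
    idx <- which(Y != 0, arr.ind = TRUE)
    data.frame(row = unname(idx[, 1]), col = unname(idx[, 2]))
  }
}
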