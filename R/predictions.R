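#' Write top-ranked predictions per side effect
#'
#' Emits a TSV with columns `side_effect`, `drug`, `score`, `rank`: for each
#' side effect (row of the score matrix) the `k_top` highest-scoring drugs in
#' descending score order, ties broken by ascending drug label so the output
#' is deterministic.
#'
#' @param scores Numeric matrix of prediction scores with side effects as
#'   rownames and drugs as colnames (e.g. `fitted(heatlink_fit)`).
#' @param k_top Number of drugs to keep per side effect (>= 1; capped at the
#'   number of drugs).
#' @param path Output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_predictions <- function(scores, k_top, path) {
  scores <- as.matrix(scores)
  stopifnot(k_top >= 1, !is.null(rownames(scores)), !is.null(colnames(scores)))
  if (any(!is.finite(scores))) stop("non-finite prediction scores")
  k <- min(as.integer(k_top), ncol(scores))
  per_row <- lapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-scores[i, ], colnames(scores))[seq_len(k)]
    data.frame(side_effect = rownames(scores)[i],
               drug = colnames(scores)[ord],
               score = scores[i, ord],
               rank = seq_len(k))
  })
  out <- do.call(rbind, per_row)
  rownames(out) <- NULL
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%.17g\t%d",
                     out$side_effect, out$drug, out$score, out$rank), con)
  invisible(out)
}

#' Read back a predictions file written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return Data frame with columns `side_effect`, `drug`, `score`, `rank`.
#' @export
read_predictions <- function(path) {
  parsed <- read_delim_lines(path)
  if (!length(parsed$fields)) {
    return(data.frame(side_effect = character(), drug = character(),
                      score = numeric(), rank = integer()))
  }
  nf <- lengths(parsed$fields)
  if (any(nf != 4)) {
    k <- which(nf != 4)[1]
    stop_bad_line(path, parsed$lineno[k], parsed$raw[k],
                  "4 fields: side_effect, drug, score, rank")
  }
  data.frame(side_effect = vapply(parsed$fields, `[`, character(1), 1),
             drug = vapply(parsed$fields, `[`, character(1), 2),
             score = as.numeric(vapply(parsed$fields, `[`, character(1), 3)),
             rank = as.integer(vapply(parsed$fields, `[`, character(1), 4)))
}
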