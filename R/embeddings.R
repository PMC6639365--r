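#' Read word vectors in word2vec text format
#'
#' The expected layout is a header line `vocab_count dim` followed by one line
#' per token: `token v1 v2 ... vdim`. Only the text format is supported.
#'
#' @param path Path to the embedding file (UTF-8).
#' @return A list of class `embedding_table` with `vocab` (character) and
#'   `vectors` (numeric matrix, one row per token, rownames = vocab).
#' @export
read_word2vec_text <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2) stop("word2vec text file must have a header and at least one vector")
  hdr <- as.integer(strsplit(trimws(lines[1]), "[\t ]+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("malformed word2vec header (expected 'vocab_count dim'): ", lines[1])
  }
  dim <- hdr[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != dim + 1)) {
    k <- which(nf != dim + 1)[1]
    stop(sprintf("malformed vector line %d: expected %d values for token '%s'",
                 k + 1L, dim, fields[[k]][1]))
  }
  vocab <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(vocab)) stop("duplicate tokens in embedding vocabulary")
  vec <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(dim)))
  if (any(!is.finite(vec))) stop("non-finite embedding values")
  rownames(vec) <- vocab
  structure(list(vocab = vocab, vectors = vec, dim = dim),
            class = "embedding_table")
}

#' Build a drug-drug similarity graph from word embeddings
#'
#' Looks each drug label up in the embedding vocabulary (case-insensitively,
#' after trimming) and connects two drugs when the cosine similarity of their
#' vectors exceeds `threshold`. Non-positive cosines never create an edge, so
#' all edge weights are strictly positive. Drugs missing from the vocabulary
#' are kept as isolated nodes (reported with a warning) so the graph stays
#' index-aligned with the biadjacency columns.
#'
#' @param emb An `embedding_table` from [read_word2vec_text()].
#' @param drugs Character vector of drug labels (unique).
#' @param threshold Similarity threshold in `[0, Inf)`; an edge requires
#'   cosine > threshold. Default 0: every positive similarity becomes an edge.
#' @return A [similarity_graph()] over `drugs`, in the given order.
#' @export
build_similarity_from_embeddings <- function(emb, drugs, threshold = 0) {
  stopifnot(inherits(emb, "embedding_table"), threshold >= 0)
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) stop("duplicate drug labels")
  key <- tolower(trimws(emb$vocab))
  hit <- match(tolower(trimws(drugs)), key)
  if (anyNA(hit)) {
    warning("drugs missing from embedding vocabulary (kept isolated): ",
            paste(drugs[is.na(hit)], collapse = ", "))
  }
  resolved <- which(!is.na(hit))
  if (length(resolved) < 2) stop("fewer than 2 drugs resolvable in the embedding vocabulary")
  V <- emb$vectors[hit[resolved], , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    stop("zero-norm embedding vector for token(s): ",
         paste(emb$vocab[hit[resolved]][nrm == 0], collapse = ", "))
  }
  C <- tcrossprod(V / nrm)
  ut <- which(upper.tri(C) & C > threshold & C > 0, arr.ind = TRUE)
  similarity_graph(drugs,
                   data.frame(from = drugs[resolved[ut[, 1]]],
                              to = drugs[resolved[ut[, 2]]],
                              weight = C[ut]),
                   quiet = TRUE)
}
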