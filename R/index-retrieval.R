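# Vector index, BM25 lexical scoring, and the serving retrieval path:
# ANN top-10 by cosine, hybrid re-ranking (min-max normalized dense + BM25,
# convex combination), top-3 evidence set with a full audit trace.

#' Index configuration
#'
#' HNSW graph degree `M` (default 32), build beam width `ef_construction`
#' (default 200), query beam width `ef_search` (default 100, must be at least
#' `k` at query time), embedding `dimension`, and the level-assignment
#' `seed`.
#'
#' @param M,ef_construction,ef_search,dimension,seed See description.
#' @return An `index_config` list.
#' @export
index_config <- function(M = 32L, ef_construction = 200L, ef_search = 100L,
                         dimension = 768L, seed = 1L) {
  stopifnot(M >= 2, ef_construction >= M, ef_search >= 1)
  structure(list(M = as.integer(M),
                 ef_construction = as.integer(ef_construction),
                 ef_search = as.integer(ef_search),
                 dimension = as.integer(dimension),
                 seed = as.integer(seed)),
            class = "index_config")
}

#' Build the HNSW vector index over chunk embeddings
#'
#' Chunks are embedded with `backend`, L2-normalized, and inserted in
#' `chunk_id` order (reproducibility). Chunks with zero-information
#' embeddings are rejected.
#'
#' @param chunks Chunk data.frame (needs `chunk_id`, `text`).
#' @param config An [index_config()].
#' @param backend A [hash_embedding_backend()].
#' @return A `vector_index` holding the graph, the embedding matrix
#'   (columns = chunks) and the id vocabulary.
#' @export
build_index <- function(chunks, config = index_config(), backend) {
  stopifnot(nrow(chunks) >= 1)
  if (config$dimension != backend$dimension) {
    stop("index dimension (", config$dimension,
         ") does not match backend dimension (", backend$dimension, ")")
  }
  ord <- order(chunks$chunk_id)
  chunks <- chunks[ord, , drop = FALSE]
  emb <- vapply(chunks$text, embed_text, numeric(backend$dimension),
                backend = backend, USE.NAMES = FALSE)
  emb <- matrix(emb, nrow = backend$dimension)
  ok <- colSums(abs(emb)) > 0
  if (!any(ok)) stop("no chunk produced a non-degenerate embedding")
  if (!all(ok)) warning(sum(!ok), " chunk(s) with zero-information embeddings dropped")
  chunks <- chunks[ok, , drop = FALSE]
  emb <- emb[, ok, drop = FALSE]
  ptr <- hnsw_build_cpp(t(emb), config$M, config$ef_construction, config$seed)
  structure(list(ptr = ptr, ids = chunks$chunk_id, embeddings = emb,
                 config = config),
            class = "vector_index")
}

#' @export
print.vector_index <- function(x, ...) {
  cat("<vector_index> ", length(x$ids), " vectors, dim=",
      x$config$dimension, ", M=", x$config$M, "\n", sep = "")
  invisible(x)
}

#' Query the index for the k nearest chunks by cosine similarity
#'
#' @param index A `vector_index`.
#' @param query A unit embedding vector.
#' @param k Number of neighbours.
#' @param ef_search Query beam width; defaults to the index config, floored
#'   at `k`.
#' @return data.frame with `chunk_id` and `similarity`, best first.
#' @export
knn_search <- function(index, query, k, ef_search = NULL) {
  ef <- max(ef_search %||% index$config$ef_search, k)
  res <- hnsw_search_cpp(index$ptr, query, as.integer(k), as.integer(ef))
  data.frame(chunk_id = index$ids[res$idx], similarity = res$similarity,
             stringsAsFactors = FALSE)
}

#' Exact k-nearest-neighbour search (brute force)
#'
#' Independent of the HNSW graph: a full matrix product against every stored
#' embedding. Used as the recall oracle and for scope-affinity scoring.
#'
#' @inheritParams knn_search
#' @export
exact_knn <- function(index, query, k) {
  sims <- as.numeric(crossprod(index$embeddings, query))
  ord <- order(-sims, index$ids)
  take <- utils::head(ord, k)
  data.frame(chunk_id = index$ids[take], similarity = sims[take],
             stringsAsFactors = FALSE)
}

# ---- BM25 ----

#' Precompute Okapi BM25 corpus statistics
#'
#' @param chunks Chunk data.frame (`chunk_id`, `text`).
#' @return A `bm25_corpus`: token lists, document lengths, document
#'   frequencies, `N` and average document length.
#' @export
bm25_corpus <- function(chunks) {
  stopifnot(nrow(chunks) >= 1)
  toks <- lapply(chunks$text, function(t) tokenize(t)$tokens)
  names(toks) <- chunks$chunk_id
  dl <- vapply(toks, length, integer(1))
  df <- table(unlist(lapply(toks, unique)))
  structure(list(tokens = toks, doc_len = dl,
                 df = df, N = length(toks), avgdl = mean(dl)),
            class = "bm25_corpus")
}

#' Okapi BM25 scores for a query
#'
#' `score(q, d) = sum_t IDF(t) f(t,d)(k1+1) / (f(t,d) + k1(1-b+b|d|/avgdl))`
#' with `IDF(t) = ln((N - df + 0.5)/(df + 0.5) + 1)` (always non-negative).
#' Statistics come from the whole corpus; scores can be restricted to a
#' candidate subset (the re-ranking use).
#'
#' @param query A `token_sequence`, string, or token vector.
#' @param corpus A [bm25_corpus()].
#' @param k1,b Okapi parameters (defaults 1.5 and 0.75).
#' @param chunk_ids Optional subset of chunk ids to score.
#' @return Named numeric vector of scores (one per scored chunk).
#' @export
bm25_scores <- function(query, corpus, k1 = 1.5, b = 0.75, chunk_ids = NULL) {
  stopifnot(inherits(corpus, "bm25_corpus"))
  q <- unique(as_tokens(query))
  ids <- chunk_ids %||% names(corpus$tokens)
  stopifnot(all(ids %in% names(corpus$tokens)))
  scores <- stats::setNames(numeric(length(ids)), ids)
  if (!length(q)) return(scores)
  dfq <- as.numeric(corpus$df[q])
  dfq[is.na(dfq)] <- 0
  idf <- log((corpus$N - dfq + 0.5) / (dfq + 0.5) + 1)
  for (id in ids) {
    toks <- corpus$tokens[[id]]
    dl <- corpus$doc_len[[id]]
    f <- vapply(q, function(t) sum(toks == t), numeric(1))
    denom <- f + k1 * (1 - b + b * dl / corpus$avgdl)
    scores[[id]] <- sum(idf * f * (k1 + 1) / denom)
  }
  scores
}

# min-max normalization within a candidate set; constant scores map to 0.5
# so they contribute no ordering information to the fusion.
minmax_norm <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

#' Hybrid-retrieval evidence set for a query
#'
#' The serving retrieval path: (1) ANN top-`k_ann` by cosine similarity;
#' (2) min-max normalize dense and BM25 scores within the candidate set;
#' (3) fuse as `alpha * dense + (1 - alpha) * bm25`; (4) keep the top
#' `k_final` by fused score (ties broken by `chunk_id`). The full candidate
#' trace is retained for auditing.
#'
#' @param query_text Patient question.
#' @param kb A knowledge-base handle from [build_kb()].
#' @param k_ann ANN candidate count (default 10).
#' @param k_final Evidence-set size (default 3).
#' @param alpha Dense weight of the convex fusion, in `[0, 1]` (default 0.5).
#' @return An `evidence_set`: `candidates` (top `k_final` with dense, BM25
#'   and fused scores plus chunk text), `trace` (all candidates), and flags.
#' @export
retrieve <- function(query_text, kb, k_ann = 10L, k_final = 3L, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  q <- embed_text(query_text, kb$backend)
  empty <- structure(list(query = query_text,
                          candidates = NULL, trace = NULL,
                          zero_information = TRUE, short_corpus = FALSE),
                     class = "evidence_set")
  if (isTRUE(attr(q, "zero_information"))) return(empty)
  n <- length(kb$index$ids)
  k <- min(k_ann, n)
  nn <- knn_search(kb$index, q, k)
  bm <- bm25_scores(query_text, kb$bm25, k1 = kb$config$retrieval$k1,
                    b = kb$config$retrieval$b, chunk_ids = nn$chunk_id)
  dense_n <- minmax_norm(nn$similarity)
  bm25_n <- minmax_norm(as.numeric(bm))
  fused <- alpha * dense_n + (1 - alpha) * bm25_n
  ord <- order(-fused, nn$chunk_id)
  trace <- data.frame(chunk_id = nn$chunk_id,
                      dense_score = nn$similarity,
                      bm25_score = as.numeric(bm),
                      fused_score = fused,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(trace) <- NULL
  cand <- utils::head(trace, k_final)
  m <- match(cand$chunk_id, kb$chunks$chunk_id)
  cand$text <- kb$chunks$text[m]
  cand$doc_id <- kb$chunks$doc_id[m]
  cand$topic <- kb$chunks$topic[m]
  structure(list(query = query_text, candidates = cand, trace = trace,
                 zero_information = FALSE, short_corpus = n < k_final),
            class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  if (isTRUE(x$zero_information)) {
    cat("<evidence_set> zero-information query\n")
  } else {
    cat("<evidence_set> top", nrow(x$candidates), "of",
        nrow(x$trace), "candidates:",
        paste(x$candidates$chunk_id, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- knowledge-base handle ----

#' Build a knowledge-base handle (chunks + index + BM25 statistics)
#'
#' @param docs List of `source_document`s (e.g. from [generate_kb()] or
#'   [load_documents()]).
#' @param config A [default_config()] list.
#' @return A `knowledge_base` handle used by [retrieve()], [route_query()]
#'   and [answer_query()].
#' @export
build_kb <- function(docs, config = default_config()) {
  chunks <- chunk_documents(docs,
                            chunk_limit = config$chunking$chunk_limit,
                            paragraph_break = config$chunking$paragraph_break,
                            paragraph_fill = config$chunking$paragraph_fill)
  backend <- hash_embedding_backend(config$embedding$dimension,
                                    config$embedding$seed)
  icfg <- index_config(M = config$index$M,
                       ef_construction = config$index$ef_construction,
                       ef_search = config$index$ef_search,
                       dimension = config$embedding$dimension,
                       seed = config$index$seed)
  idx <- build_index(chunks, icfg, backend)
  structure(list(documents = docs, chunks = chunks, index = idx,
                 bm25 = bm25_corpus(chunks), backend = backend,
                 scope = scope_statistics(chunks), config = config),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ", length(x$documents), " documents, ",
      nrow(x$chunks), " chunks, dim=", x$backend$dimension, "\n", sep = "")
  invisible(x)
}
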