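make_unit_matrix <- function(n, d, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  x / sqrt(rowSums(x^2))
}

test_that("hashed embeddings are deterministic unit vectors of the set dimension", {
  be <- hash_embedding_backend(768L, seed = 1L)
  v1 <- embed_text("wound care after surgery", be)
  v2 <- embed_text("wound care after surgery", be)
  expect_identical(v1, v2)
  expect_length(v1, 768L)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-9)
  z <- embed_text("", be)
  expect_true(isTRUE(attr(z, "zero_information")))
})

test_that("embedding similarity reflects token overlap (brute-force cosine)", {
  be <- hash_embedding_backend(256L, seed = 3L)
  a <- embed_text("wound care dressing", be)
  b <- embed_text("wound care", be)
  c <- embed_text("airline seat upgrade", be)
  expect_gt(sum(a * b), sum(a * c))
  # cross-check against explicitly constructed token-hash vectors
  manual <- function(tokens) {
    m <- ragcare:::token_vectors(be, tokens)
    v <- rowSums(m)
    v / sqrt(sum(v^2))
  }
  expect_equal(as.numeric(sum(a * b)),
               sum(manual(c("wound", "care", "dressing")) *
                   manual(c("wound", "care"))),
               tolerance = 1e-10)
})

test_that("index self-retrieval returns the query vector first at cosine 1", {
  X <- make_unit_matrix(200, 64, seed = 2)
  cfg <- index_config(M = 16L, ef_construction = 100L, ef_search = 100L,
                      dimension = 64L, seed = 1L)
  ptr <- ragcare:::hnsw_build_cpp(X, cfg$M, cfg$ef_construction, cfg$seed)
  idx <- structure(list(ptr = ptr, ids = sprintf("c%03d", 1:200),
                        embeddings = t(X), config = cfg),
                   class = "vector_index")
  for (i in c(1, 57, 200)) {
    r <- knn_search(idx, X[i, ], 1L)
    expect_equal(r$chunk_id, sprintf("c%03d", i))
    expect_equal(r$similarity, 1, tolerance = 1e-9)
  }
})

test_that("HNSW recall@10 is at least 0.95 against exact k-NN on 1,000 vectors", {
  X <- make_unit_matrix(1000, 64, seed = 42)
  cfg <- index_config(M = 32L, ef_construction = 200L, ef_search = 100L,
                      dimension = 64L, seed = 1L)
  ptr <- ragcare:::hnsw_build_cpp(X, cfg$M, cfg$ef_construction, cfg$seed)
  idx <- structure(list(ptr = ptr, ids = sprintf("v%04d", 1:1000),
                        embeddings = t(X), config = cfg),
                   class = "vector_index")
  queries <- seq(5, 1000, by = 20)
  recall <- vapply(queries, function(i) {
    approx <- knn_search(idx, X[i, ], 10L)
    exact <- exact_knn(idx, X[i, ], 10L)
    length(intersect(approx$chunk_id, exact$chunk_id)) / 10
  }, numeric(1))
  expect_gte(mean(recall), 0.95)
})

test_that("with ef_search at corpus size HNSW equals exact k-NN on small corpora", {
  X <- make_unit_matrix(300, 32, seed = 9)
  cfg <- index_config(M = 16L, ef_construction = 100L, ef_search = 300L,
                      dimension = 32L, seed = 4L)
  ptr <- ragcare:::hnsw_build_cpp(X, cfg$M, cfg$ef_construction, cfg$seed)
  idx <- structure(list(ptr = ptr, ids = sprintf("c%03d", 1:300),
                        embeddings = t(X), config = cfg),
                   class = "vector_index")
  for (i in c(3, 111, 222)) {
    expect_identical(knn_search(idx, X[i, ], 5L, ef_search = 300L)$chunk_id,
                     exact_knn(idx, X[i, ], 5L)$chunk_id)
  }
})

test_that("index configuration is validated and defaults match the design", {
  cfg <- index_config()
  expect_equal(cfg$M, 32L)
  expect_equal(cfg$ef_construction, 200L)
  expect_equal(cfg$dimension, 768L)
  expect_error(index_config(M = 1L))
  expect_error(index_config(M = 32L, ef_construction = 10L))
})

test_that("BM25 matches direct formula evaluation on a toy corpus", {
  chunks <- data.frame(
    chunk_id = c("d1", "d2", "d3"),
    text = c("wound care wound", "wound care", "drain care"),
    stringsAsFactors = FALSE)
  corp <- bm25_corpus(chunks)
  got <- bm25_scores("wound", corp)
  toks <- list(c("wound", "care", "wound"), c("wound", "care"),
               c("drain", "care"))
  expect_equal(unname(got), oracle_bm25("wound", toks), tolerance = 1e-12)
  # zero-match term contributes nothing
  expect_equal(unname(bm25_scores("zebra", corp)), c(0, 0, 0))
  # identical chunks score identically
  twin <- bm25_corpus(data.frame(chunk_id = c("a", "b"),
                                 text = c("wound care", "wound care"),
                                 stringsAsFactors = FALSE))
  tw <- bm25_scores("wound care", twin)
  expect_equal(tw[["a"]], tw[["b"]])
})

test_that("hybrid fusion follows min-max + convex combination with tie-break", {
  dense <- c(0.9, 0.5, 0.1)
  bm <- c(1, 3, 2)
  dn <- ragcare:::minmax_norm(dense)
  bn <- ragcare:::minmax_norm(bm)
  fused <- 0.5 * dn + 0.5 * bn
  expect_equal(fused, c(0.5, 0.75, 0.25))
  expect_equal(order(-fused), c(2, 1, 3))
  # min-max of a constant vector carries no ordering information
  expect_equal(ragcare:::minmax_norm(c(2, 2, 2)), c(0.5, 0.5, 0.5))
})

test_that("retrieve returns a top-3 evidence set with a full trace", {
  kb <- build_kb(toy_docs(), toy_config())
  ev <- retrieve("When can I shower after surgery?", kb)
  expect_s3_class(ev, "evidence_set")
  expect_equal(nrow(ev$candidates), 3L)
  expect_gte(nrow(ev$trace), nrow(ev$candidates))
  expect_true(all(ev$candidates$chunk_id %in% kb$chunks$chunk_id))
  expect_true(all(diff(ev$candidates$fused_score) <= 0))
  # the showering chunk must surface
  expect_true(any(grepl("toy-02", ev$candidates$chunk_id)))
})

test_that("fusion endpoints reduce to pure dense and pure BM25 rankings", {
  kb <- build_kb(toy_docs(), toy_config())
  q <- "compression stockings for travel"
  ev1 <- retrieve(q, kb, alpha = 1)
  expect_equal(ev1$trace$chunk_id,
               ev1$trace$chunk_id[order(-ev1$trace$dense_score,
                                        ev1$trace$chunk_id)])
  ev0 <- retrieve(q, kb, alpha = 0)
  expect_equal(ev0$trace$chunk_id,
               ev0$trace$chunk_id[order(-ev0$trace$bm25_score,
                                        ev0$trace$chunk_id)])
})

test_that("fused ranking is invariant under affine rescaling of BM25", {
  kb <- build_kb(toy_docs(), toy_config())
  ev <- retrieve("driving and long car rides", kb)
  dn <- ragcare:::minmax_norm(ev$trace$dense_score)
  bn1 <- ragcare:::minmax_norm(ev$trace$bm25_score)
  bn2 <- ragcare:::minmax_norm(3.7 * ev$trace$bm25_score + 11)
  expect_equal(bn1, bn2, tolerance = 1e-12)
})

test_that("retrieval is deterministic and flags degenerate inputs", {
  kb <- build_kb(toy_docs(), toy_config())
  e1 <- retrieve("drain care at home", kb)
  e2 <- retrieve("drain care at home", kb)
  expect_identical(e1$candidates, e2$candidates)
  ez <- retrieve("!!! ???", kb)
  expect_true(ez$zero_information)
})
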