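# Deterministic hashed bag-of-tokens embedding backend. Each vocabulary
# token maps, via a seeded string hash, to a fixed pseudo-random unit vector;
# a text embeds as the L2-normalized sum of its token vectors weighted by
# sublinear term frequency (1 + log tf). No model download, same text ->
# identical vector. Any external embedding service can be plugged in behind
# the same contract (a function text -> numeric vector of the configured
# dimension).

#' Polynomial string hash
#'
#' Deterministic 31-polynomial hash modulo 2^31 - 1, independent of the R
#' session. Used to derive per-token RNG seeds.
#'
#' @param x Character vector.
#' @return Integer vector of non-negative hashes.
#' @export
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(enc2utf8(s))) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

with_preserved_rng <- function(code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
      rm(".Random.seed", envir = ge)
    }
  })
  force(code)
}

#' Create the deterministic hashed embedding backend
#'
#' @param dimension Embedding dimension (default 768).
#' @param seed Integer seed mixed into every token hash, so different seeds
#'   give unrelated embedding spaces.
#' @return A `hash_embedding_backend` handle with a token-vector cache.
#' @export
hash_embedding_backend <- function(dimension = 768L, seed = 1L) {
  stopifnot(dimension >= 2, is.numeric(seed))
  structure(list(dimension = as.integer(dimension), seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = "hash_embedding_backend")
}

#' @export
print.hash_embedding_backend <- function(x, ...) {
  cat("<hash_embedding_backend> dim=", x$dimension, " seed=", x$seed,
      " cached=", length(ls(x$cache)), " tokens\n", sep = "")
  invisible(x)
}

token_vectors <- function(backend, tokens) {
  out <- matrix(0, nrow = backend$dimension, ncol = length(tokens))
  miss <- !vapply(tokens, exists, logical(1), envir = backend$cache,
                  inherits = FALSE)
  if (any(miss)) {
    hashes <- string_hash(tokens[miss])
    with_preserved_rng({
      for (i in seq_along(hashes)) {
        s <- (as.double(hashes[i]) * 97 + backend$seed * 1000003) %% 2147483647
        set.seed(as.integer(s))
        v <- stats::rnorm(backend$dimension)
        assign(tokens[miss][i], v / sqrt(sum(v^2)), envir = backend$cache)
      }
    })
  }
  for (i in seq_along(tokens)) {
    out[, i] <- get(tokens[i], envir = backend$cache, inherits = FALSE)
  }
  out
}

embed_token_bag <- function(backend, tokens) {
  if (!length(tokens)) {
    return(structure(numeric(backend$dimension), zero_information = TRUE))
  }
  tf <- table(tokens)
  vocab <- names(tf)
  w <- 1 + log(as.numeric(tf))
  v <- as.numeric(token_vectors(backend, vocab) %*% w)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) {
    return(structure(numeric(backend$dimension), zero_information = TRUE))
  }
  v / nrm
}

#' Embed a text as a dense unit vector
#'
#' @param text A length-one character string.
#' @param backend A [hash_embedding_backend()] (or any object with the same
#'   contract).
#' @return A numeric vector of length `backend$dimension`, L2-normalized.
#'   Texts with no tokens return a zero vector carrying attribute
#'   `zero_information = TRUE`; such vectors are rejected by the index.
#' @export
embed_text <- function(text, backend) {
  embed_token_bag(backend, tokenize(text)$tokens)
}
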