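# Automated response-quality battery: the two-stage hybrid evaluation
# retriever (dense + MMR diversification, then BM25 union, fused top-k over
# 300-word chunks), fuzzy-Jaccard groundedness (context precision, context
# recall, faithfulness), n-gram fluency metrics (BLEU, ROUGE-1/2/L, and a
# hash-embedding analogue of BERTScore), and readability / language
# structure metrics (Flesch-Kincaid).

#' Re-chunk documents by word count for the evaluation retriever
#'
#' Same sentence-packing rule as serving ingestion, but the budget is
#' counted in word tokens (default 300) instead of characters — the
#' evaluation retriever deliberately sees a different segmentation than the
#' serving index.
#'
#' @param docs List of `source_document`s.
#' @param chunk_words Word budget per chunk (default 300).
#' @return Chunk data.frame (same shape as [chunk_documents()]).
#' @export
chunk_by_words <- function(docs, chunk_words = 300L) {
  stopifnot(chunk_words >= 20)
  out <- lapply(docs, function(doc) {
    sl <- split_sentences(doc$body)
    ns <- length(sl$sentences)
    if (!ns) stop("document has no sentences: ", doc$doc_id)
    wc <- vapply(sl$sentences, function(s) length(tokenize(s)$tokens),
                 integer(1))
    groups <- list(); cur <- integer(0); cur_w <- 0L
    for (i in seq_len(ns)) {
      if (length(cur) && cur_w + wc[i] > chunk_words) {
        groups[[length(groups) + 1L]] <- cur
        cur <- integer(0); cur_w <- 0L
      }
      cur <- c(cur, i); cur_w <- cur_w + wc[i]
    }
    if (length(cur)) groups[[length(groups) + 1L]] <- cur
    do.call(rbind, lapply(seq_along(groups), function(g) {
      idx <- groups[[g]]
      s0 <- sl$start[idx[1]]; e0 <- sl$end[idx[length(idx)]]
      txt <- substring(doc$body, s0, e0 - 1L)
      data.frame(chunk_id = sprintf("%s-w%03d", doc$doc_id, g),
                 doc_id = doc$doc_id, topic = doc$topic, text = txt,
                 start = s0, end = e0,
                 token_count = length(tokenize(txt)$tokens),
                 overflow = FALSE, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Build the evaluation knowledge-base handle (300-word chunks)
#'
#' @param docs List of `source_document`s.
#' @param config Configuration list.
#' @return An `eval_kb` with word chunks, their embeddings and BM25 stats.
#' @export
build_eval_kb <- function(docs, config = default_config()) {
  chunks <- chunk_by_words(docs, config$evaluation$chunk_words)
  backend <- hash_embedding_backend(config$embedding$dimension,
                                    config$embedding$seed)
  emb <- vapply(chunks$text, embed_text, numeric(backend$dimension),
                backend = backend, USE.NAMES = FALSE)
  structure(list(chunks = chunks, embeddings = matrix(emb, nrow = backend$dimension),
                 bm25 = bm25_corpus(chunks), backend = backend,
                 config = config),
            class = "eval_kb")
}

# Maximal marginal relevance selection over a candidate set.
# MMR(d) = lambda * sim(q, d) - (1 - lambda) * max_{d' in S} sim(d, d')
mmr_select <- function(query_sims, cand_sims, n_select, lambda) {
  nc <- length(query_sims)
  n_select <- min(n_select, nc)
  selected <- integer(0)
  remaining <- seq_len(nc)
  while (length(selected) < n_select) {
    red <- if (!length(selected)) {
      numeric(length(remaining))
    } else {
      apply(cand_sims[remaining, selected, drop = FALSE], 1, max)
    }
    score <- lambda * query_sims[remaining] - (1 - lambda) * red
    pick <- remaining[order(-score, remaining)[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Two-stage hybrid evaluation retriever
#'
#' Stage 1: dense top-`2k` by cosine with maximal-marginal-relevance
#' diversification (`MMR(d) = lambda sim(q,d) - (1-lambda) max_{d' in S}
#' sim(d,d')`). Stage 2: union with the BM25 top-`2k`. The union is fused
#' (min-max + convex combination) and the top `k` returned.
#'
#' @param question Query text.
#' @param eval_kb From [build_eval_kb()].
#' @param k Final evidence count (default from config, 4).
#' @param mmr_lambda Relevance/redundancy trade-off in `[0, 1]` (default
#'   from config, 0.7).
#' @return data.frame of selected chunks with scores.
#' @export
eval_retrieve <- function(question, eval_kb, k = NULL, mmr_lambda = NULL) {
  stopifnot(inherits(eval_kb, "eval_kb"))
  cfg <- eval_kb$config$evaluation
  k <- k %||% cfg$k
  mmr_lambda <- mmr_lambda %||% cfg$mmr_lambda
  n <- nrow(eval_kb$chunks)
  if (!n) stop("empty evaluation knowledge base")
  q <- embed_text(question, eval_kb$backend)
  dense <- as.numeric(crossprod(eval_kb$embeddings, q))
  pool <- order(-dense, eval_kb$chunks$chunk_id)
  pool <- utils::head(pool, max(4L * k, 2L * k + 2L))
  cand_sims <- crossprod(eval_kb$embeddings[, pool, drop = FALSE])
  s1 <- pool[mmr_select(dense[pool], cand_sims, 2L * k, mmr_lambda)]
  bm <- bm25_scores(question, eval_kb$bm25)
  s2 <- order(-bm, eval_kb$chunks$chunk_id)
  s2 <- utils::head(s2, 2L * k)
  union_idx <- sort(unique(c(s1, s2)))
  dn <- minmax_norm(dense[union_idx])
  bn <- minmax_norm(as.numeric(bm)[union_idx])
  fused <- 0.5 * dn + 0.5 * bn
  ord <- order(-fused, eval_kb$chunks$chunk_id[union_idx])
  take <- union_idx[utils::head(ord, k)]
  data.frame(chunk_id = eval_kb$chunks$chunk_id[take],
             text = eval_kb$chunks$text[take],
             dense_score = dense[take],
             bm25_score = as.numeric(bm)[take],
             stringsAsFactors = FALSE)
}

# sentence-support helper: max fuzzy Jaccard of `sentence` against any
# sentence of any text in `texts`
max_sentence_support <- function(sentence, sentence_tokens, match_threshold) {
  st <- tokenize(sentence)$tokens
  if (!length(sentence_tokens)) return(0)
  max(vapply(sentence_tokens, function(et) {
    as.numeric(fuzzy_jaccard(st, et, match_threshold))
  }, numeric(1)))
}

#' Groundedness of one answer against retrieved evidence
#'
#' Three fuzzy-Jaccard metrics at support threshold `tau_support`. The
#' sentence is the unit of support throughout: two sentences support each
#' other when their fuzzy Jaccard reaches the threshold.
#' * context precision — fraction of retrieved chunks with at least one
#'   sentence supporting a gold-passage sentence;
#' * context recall — fraction of gold-passage sentences supported by some
#'   retrieved evidence sentence;
#' * faithfulness — fraction of answer sentences supported by some
#'   retrieved evidence sentence.
#'
#' @param answer Answer text.
#' @param gold_passage The knowledge-base span the answer must be grounded
#'   in.
#' @param retrieved Character vector of retrieved chunk texts.
#' @param tau_support Support threshold (default 0.35).
#' @param match_threshold Fuzzy token tolerance (default 0.85).
#' @return List: `context_precision`, `context_recall`, `faithfulness`.
#' @export
groundedness <- function(answer, gold_passage, retrieved,
                         tau_support = 0.35, match_threshold = 0.85) {
  stopifnot(nzchar(answer), nzchar(gold_passage), length(retrieved) >= 1)
  ev_sent <- unlist(lapply(retrieved, function(t) split_sentences(t)$sentences),
                    use.names = FALSE)
  ev_tokens <- lapply(ev_sent, function(s) tokenize(s)$tokens)
  gs <- split_sentences(gold_passage)$sentences
  gs_tokens <- lapply(gs, function(s) tokenize(s)$tokens)
  cp <- mean(vapply(retrieved, function(ch) {
    cs <- split_sentences(ch)$sentences
    any(vapply(cs, function(s) {
      max_sentence_support(s, gs_tokens, match_threshold) >= tau_support
    }, logical(1)))
  }, logical(1)))
  cr <- mean(vapply(gs, function(s) {
    max_sentence_support(s, ev_tokens, match_threshold) >= tau_support
  }, logical(1)))
  as_ <- split_sentences(answer)$sentences
  faith <- mean(vapply(as_, function(s) {
    max_sentence_support(s, ev_tokens, match_threshold) >= tau_support
  }, logical(1)))
  list(context_precision = cp, context_recall = cr, faithfulness = faith)
}

#' Batch groundedness report
#'
#' @param items List of lists with `answer`, `gold_passage`, `retrieved`.
#' @inheritParams groundedness
#' @return A `groundedness_report`: batch means, the hallucination rate
#'   (`1 - faithfulness`), and per-item details.
#' @export
groundedness_report <- function(items, tau_support = 0.35,
                                match_threshold = 0.85) {
  per <- lapply(items, function(it) {
    groundedness(it$answer, it$gold_passage, it$retrieved,
                 tau_support, match_threshold)
  })
  cp <- mean(vapply(per, `[[`, numeric(1), "context_precision"))
  cr <- mean(vapply(per, `[[`, numeric(1), "context_recall"))
  ft <- mean(vapply(per, `[[`, numeric(1), "faithfulness"))
  structure(list(context_precision = cp, context_recall = cr,
                 faithfulness = ft, hallucination_rate = 1 - ft,
                 items = per),
            class = "groundedness_report")
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1))
}

clipped_overlap <- function(cand, ref) {
  tc <- table(cand); tr <- table(ref)
  shared <- intersect(names(tc), names(tr))
  sum(pmin(as.numeric(tc[shared]), as.numeric(tr[shared])))
}

#' BLEU score (n <= 4, uniform weights, brevity penalty)
#'
#' Modified n-gram precisions with add-one smoothing for orders >= 2 (short
#' texts would otherwise zero out), geometric mean over orders 1..4, and the
#' standard brevity penalty. Identity scores 1; token-disjoint pairs 0.
#'
#' @param candidate,reference Texts.
#' @return A number in `[0, 1]`.
#' @export
bleu_score <- function(candidate, reference) {
  ct <- tokenize(candidate)$tokens
  rt <- tokenize(reference)$tokens
  if (!length(ct) || !length(rt)) return(0)
  logp <- 0
  for (n in 1:4) {
    cn <- ngrams(ct, n); rn <- ngrams(rt, n)
    m <- clipped_overlap(cn, rn)
    tot <- length(cn)
    p <- if (n == 1) {
      if (tot == 0) 0 else m / tot
    } else {
      (m + 1) / (tot + 1)
    }
    if (p == 0) return(0)
    logp <- logp + log(p) / 4
  }
  bp <- if (length(ct) >= length(rt)) 1 else exp(1 - length(rt) / length(ct))
  bp * exp(logp)
}

rouge_f1 <- function(m, nc, nr) {
  if (m == 0 || nc == 0 || nr == 0) return(0)
  p <- m / nc; r <- m / nr
  2 * p * r / (p + r)
}

#' ROUGE-N F1 (clipped n-gram overlap)
#'
#' @param candidate,reference Texts.
#' @param n N-gram order.
#' @return F1 in `[0, 1]`.
#' @export
rouge_n <- function(candidate, reference, n = 1L) {
  cn <- ngrams(tokenize(candidate)$tokens, n)
  rn <- ngrams(tokenize(reference)$tokens, n)
  rouge_f1(clipped_overlap(cn, rn), length(cn), length(rn))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L F1 (longest common subsequence)
#'
#' @param candidate,reference Texts.
#' @return F1 in `[0, 1]`.
#' @export
rouge_l <- function(candidate, reference) {
  ct <- tokenize(candidate)$tokens
  rt <- tokenize(reference)$tokens
  rouge_f1(lcs_length(ct, rt), length(ct), length(rt))
}

#' Hash-embedding analogue of BERTScore F1
#'
#' Greedy token-embedding matching (max cosine per token, both directions)
#' using the deterministic hashed backend. Explicitly NOT comparable to
#' published BERTScore values — it is a pluggable slot for a real contextual
#' model, reported as `bertscore_hash_f1`.
#'
#' @param candidate,reference Texts.
#' @param backend A [hash_embedding_backend()].
#' @return F1-style score in `[-1, 1]` (in practice `[0, 1]`).
#' @export
bertscore_hash <- function(candidate, reference,
                           backend = hash_embedding_backend()) {
  ct <- tokenize(candidate)$tokens
  rt <- tokenize(reference)$tokens
  if (!length(ct) || !length(rt)) return(0)
  vc <- token_vectors(backend, ct)
  vr <- token_vectors(backend, rt)
  S <- crossprod(vc, vr)
  p <- mean(apply(S, 1, max))
  r <- mean(apply(S, 2, max))
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Fluency metrics for one candidate/reference pair
#'
#' @param candidate,reference Non-empty texts.
#' @param backend Embedding backend for the BERTScore analogue.
#' @return List: `bleu`, `rouge1`, `rouge2`, `rougeL`,
#'   `bertscore_hash_f1`.
#' @export
fluency <- function(candidate, reference,
                    backend = hash_embedding_backend()) {
  stopifnot(nzchar(candidate), nzchar(reference))
  list(bleu = bleu_score(candidate, reference),
       rouge1 = rouge_n(candidate, reference, 1L),
       rouge2 = rouge_n(candidate, reference, 2L),
       rougeL = rouge_l(candidate, reference),
       bertscore_hash_f1 = bertscore_hash(candidate, reference, backend))
}

# Rule-based syllable counter: vowel-group counting with a silent-e rule and
# a small exception table. Deterministic; no dictionary dependence.
.syllable_exceptions <- c(area = 3L, aria = 3L, being = 2L, doing = 2L,
                          going = 2L, ion = 2L, quiet = 2L, science = 2L,
                          every = 2L, evening = 2L)

count_syllables <- function(word) {
  w <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (!nzchar(w)) return(0L)
  if (w %in% names(.syllable_exceptions)) {
    return(unname(.syllable_exceptions[[w]]))
  }
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  # silent final e ("care", "dose") but not "-le" after a consonant ("table")
  if (n > 1L && grepl("e$", w) && !grepl("[^aeiou]le$", w) &&
      !grepl("[aeiouy]e$", w)) {
    n <- n - 1L
  }
  max(n, 1L)
}

#' Readability and language-structure metrics
#'
#' Flesch-Kincaid Grade Level `0.39 (words/sentences) + 11.8
#' (syllables/words) - 15.59`, Flesch Reading Ease `206.835 - 1.015
#' (words/sentences) - 84.6 (syllables/words)`, plus word/sentence counts,
#' lexical diversity (unique/total tokens), punctuation ratio and a 3-bin
#' reading level (FKGL <= 12 high school or below, (12, 16] college, > 16
#' college graduate).
#'
#' @param text Non-empty text with at least one sentence.
#' @return A `readability_report` list.
#' @export
readability <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  sl <- split_sentences(text)
  if (!length(sl$sentences)) stop("text has no sentences")
  toks <- tokenize(text)$tokens
  if (!length(toks)) stop("text has no words")
  syl <- sum(vapply(toks, count_syllables, integer(1)))
  wps <- length(toks) / length(sl$sentences)
  spw <- syl / length(toks)
  fkgl <- 0.39 * wps + 11.8 * spw - 15.59
  fre <- 206.835 - 1.015 * wps - 84.6 * spw
  level <- if (fkgl <= 12) "high_school_or_below" else if (fkgl <= 16) {
    "college"
  } else "college_graduate"
  structure(list(
    word_count = length(toks),
    sentence_count = length(sl$sentences),
    words_per_sentence = wps,
    chars_per_word = mean(nchar(toks)),
    syllables_per_word = spw,
    lexical_diversity = length(unique(toks)) / length(toks),
    punctuation_ratio = lengths(regmatches(text, gregexpr("[[:punct:]]", text))) /
      nchar(text),
    fk_grade = fkgl,
    flesch_reading_ease = fre,
    level_bin = level), class = "readability_report")
}

#' Batch readability summary
#'
#' @param texts Character vector of texts.
#' @return List of per-field means plus the reading-level distribution
#'   (fractions summing to 1).
#' @export
readability_batch <- function(texts) {
  reps <- lapply(texts, readability)
  num_fields <- c("word_count", "sentence_count", "words_per_sentence",
                  "chars_per_word", "syllables_per_word",
                  "lexical_diversity", "punctuation_ratio", "fk_grade",
                  "flesch_reading_ease")
  means <- lapply(num_fields, function(f) {
    mean(vapply(reps, function(r) as.numeric(r[[f]]), numeric(1)))
  })
  names(means) <- num_fields
  bins <- factor(vapply(reps, `[[`, "", "level_bin"),
                 levels = c("high_school_or_below", "college",
                            "college_graduate"))
  c(means, list(level_distribution = prop.table(table(bins))))
}
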