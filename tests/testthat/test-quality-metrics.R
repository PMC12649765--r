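eval_kb_cache <- local({
  e <- NULL
  function() {
    if (is.null(e)) e <<- build_eval_kb(generate_kb(1), default_config(1))
    e
  }
})

test_that("word chunking respects the word budget without splitting sentences", {
  ek <- eval_kb_cache()
  chunks <- ek$chunks
  expect_true(all(chunks$token_count <= 300 |
                    vapply(chunks$text, function(t) {
                      length(split_sentences(t)$sentences) == 1
                    }, logical(1))))
  for (d in unique(chunks$doc_id)) {
    ch <- chunks[chunks$doc_id == d, ]
    expect_true(all(diff(ch$start) > 0))
  }
})

test_that("MMR selection equals exhaustive step-by-step enumeration", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 6
    q <- runif(n)
    S <- matrix(runif(n * n), n); S <- (S + t(S)) / 2; diag(S) <- 1
    lambda <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(ragcare:::mmr_select(q, S, 4, lambda),
                 oracle_mmr(q, S, 4, lambda))
  }
})

test_that("MMR endpoints and redundancy behave as designed", {
  q <- c(0.9, 0.8, 0.7, 0.6)
  S <- diag(4); S[1, 2] <- S[2, 1] <- 0.99  # 2 nearly duplicates 1
  # lambda = 1: pure similarity order
  expect_equal(ragcare:::mmr_select(q, S, 4, 1), order(-q))
  # lambda < 1: the duplicate is demoted below diverse candidates
  sel <- ragcare:::mmr_select(q, S, 4, 0.5)
  expect_gt(which(sel == 2), 2)
})

test_that("eval retriever surfaces the gold chunk for anchored questions", {
  ek <- eval_kb_cache()
  got <- eval_retrieve("How often do I need to empty my surgical drain?", ek)
  expect_lte(nrow(got), default_config()$evaluation$k)
  expect_true(any(grepl("^kb-03", got$chunk_id)))
  expect_identical(got, eval_retrieve("How often do I need to empty my surgical drain?", ek))
})

test_that("groundedness identity and disjoint limits hold", {
  chunk <- paste("You may shower 48 hours after surgery.",
                 "Pat the incision dry with a clean towel.")
  g <- groundedness(chunk, chunk, chunk)
  expect_equal(g$context_precision, 1)
  expect_equal(g$context_recall, 1)
  expect_equal(g$faithfulness, 1)
  g0 <- groundedness("Stocks rallied on strong quarterly earnings.",
                     chunk, chunk)
  expect_equal(g0$faithfulness, 0)
})

test_that("groundedness equals the brute-force sentence-by-chunk oracle", {
  retrieved <- c(paste("Keep the incision dry for 48 hours.",
                       "Change the dressing once daily."),
                 paste("Walk for 5 to 10 minutes, 4 to 6 times daily.",
                       "Short naps are fine."),
                 "No baths, hot tubs, or pools until 3 weeks after surgery.")
  gold <- paste("Keep the incision dry for 48 hours.",
                "Walk for 5 to 10 minutes, 4 to 6 times daily.")
  answer <- paste("Keep the incision dry for 48 hours.",
                  "Invest your savings in diversified index funds.")
  g <- groundedness(answer, gold, retrieved, tau_support = 0.35)
  ev_sent <- unlist(lapply(retrieved, function(t) split_sentences(t)$sentences))
  support <- function(s) {
    max(vapply(ev_sent, function(e) {
      oracle_fuzzy_jaccard(tokenize(s)$tokens, tokenize(e)$tokens, 0.85)
    }, numeric(1)))
  }
  exp_faith <- mean(vapply(split_sentences(answer)$sentences,
                           function(s) support(s) >= 0.35, logical(1)))
  exp_recall <- mean(vapply(split_sentences(gold)$sentences,
                            function(s) support(s) >= 0.35, logical(1)))
  gold_sent <- split_sentences(gold)$sentences
  exp_prec <- mean(vapply(retrieved, function(ch) {
    any(vapply(split_sentences(ch)$sentences, function(s) {
      max(vapply(gold_sent, function(g) {
        oracle_fuzzy_jaccard(tokenize(s)$tokens, tokenize(g)$tokens, 0.85)
      }, numeric(1))) >= 0.35
    }, logical(1)))
  }, logical(1)))
  expect_equal(g$faithfulness, exp_faith)
  expect_equal(g$context_recall, exp_recall)
  expect_equal(g$context_precision, exp_prec)
  expect_equal(g$faithfulness, 0.5)
})

test_that("faithfulness is non-increasing in the support threshold", {
  retrieved <- c("Keep the incision dry for 48 hours after surgery.",
                 "Change the dressing once daily with clean hands.")
  answer <- paste("Keep the incision mostly dry for about 48 hours.",
                  "Change your dressing every single day.")
  taus <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  f <- vapply(taus, function(t) {
    groundedness(answer, retrieved[1], retrieved, tau_support = t)$faithfulness
  }, numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("batch groundedness equals the mean of item metrics", {
  items <- list(
    list(answer = "Keep the incision dry for 48 hours.",
         gold_passage = "Keep the incision dry for 48 hours.",
         retrieved = "Keep the incision dry for 48 hours."),
    list(answer = "Quantum finance is the future.",
         gold_passage = "Keep the incision dry for 48 hours.",
         retrieved = "Keep the incision dry for 48 hours."))
  rep <- groundedness_report(items)
  expect_equal(rep$faithfulness,
               mean(vapply(rep$items, `[[`, numeric(1), "faithfulness")))
  expect_equal(rep$hallucination_rate, 1 - rep$faithfulness)
})

test_that("BLEU and ROUGE identity / disjoint limits", {
  s <- "Keep the incision dry for 48 hours after surgery today."
  expect_equal(bleu_score(s, s), 1)
  expect_equal(rouge_n(s, s, 1), 1)
  expect_equal(rouge_n(s, s, 2), 1)
  expect_equal(rouge_l(s, s), 1)
  expect_equal(bleu_score("alpha beta gamma", "delta epsilon zeta"), 0)
  expect_equal(rouge_n("alpha beta", "delta epsilon", 1), 0)
})

test_that("ROUGE-1 matches hand-counted n-gram arithmetic", {
  # ("the cat sat", "the cat sat down"): overlap 3, P = 1, R = 3/4
  expect_equal(rouge_n("the cat sat", "the cat sat down", 1), 6 / 7)
  # bigrams: overlap 2 of 2 and 3
  expect_equal(rouge_n("the cat sat", "the cat sat down", 2),
               2 * 1 * (2 / 3) / (1 + 2 / 3))
})

test_that("ROUGE-L uses the LCS and dominates ROUGE-2 on random pairs", {
  a <- "keep the wound clean and dry every day"
  b <- "keep your wound dry and clean each morning"
  ta <- tokenize(a)$tokens; tb <- tokenize(b)$tokens
  lcs <- oracle_lcs(ta, tb)
  p <- lcs / length(ta); r <- lcs / length(tb)
  expect_equal(rouge_l(a, b), 2 * p * r / (p + r))
  set.seed(23)
  vocab <- c("rest", "walk", "heal", "dry", "clean", "daily", "wound",
             "after", "surgery", "water")
  for (rep in 1:20) {
    x <- paste(sample(vocab, sample(4:9, 1), replace = TRUE), collapse = " ")
    y <- paste(sample(vocab, sample(4:9, 1), replace = TRUE), collapse = " ")
    expect_gte(rouge_l(x, y) + 1e-12, rouge_n(x, y, 2))
  }
})

test_that("BLEU brevity penalty punishes short candidates", {
  ref <- "keep the incision dry for 48 hours after surgery"
  expect_lt(bleu_score("keep the incision dry", ref),
            bleu_score(ref, ref))
})

test_that("the hash BERTScore analogue hits 1 on identity", {
  be <- hash_embedding_backend(128, 5)
  expect_equal(bertscore_hash("wound care daily", "wound care daily", be), 1,
               tolerance = 1e-9)
  f <- fluency("wound care daily", "wound care daily", be)
  expect_equal(f$bleu, 1)
  expect_equal(f$rouge1, 1)
})

test_that("readability reproduces direct formula evaluation", {
  r <- readability("The cat sat on the mat.")
  expect_equal(r$word_count, 6L)
  expect_equal(r$sentence_count, 1L)
  expect_equal(r$syllables_per_word, 1)
  expect_equal(r$flesch_reading_ease, 116.145)
  expect_equal(r$fk_grade, -1.45)
  expect_equal(r$level_bin, "high_school_or_below")
})

test_that("self-concatenation leaves the readability ratios unchanged", {
  tx <- "Keep the incision dry for 48 hours. Walk a little every day."
  r1 <- readability(tx)
  r2 <- readability(paste(tx, tx))
  expect_equal(r1$words_per_sentence, r2$words_per_sentence)
  expect_equal(r1$syllables_per_word, r2$syllables_per_word)
  expect_equal(r1$fk_grade, r2$fk_grade)
})

test_that("more syllables per word moves FRE and FKGL in opposite directions", {
  simple <- "The cat sat on the mat and ate."
  complex <- "Consequently, postoperative rehabilitation necessitates considerable perseverance."
  rs <- readability(simple); rc <- readability(complex)
  expect_gt(rc$fk_grade, rs$fk_grade)
  expect_lt(rc$flesch_reading_ease, rs$flesch_reading_ease)
})

test_that("reading-level distribution partitions the batch", {
  b <- readability_batch(c("The cat sat on the mat.",
                           "Consequently, rehabilitation necessitates perseverance and considerable determination throughout convalescence.",
                           "Walk a little every day after surgery."))
  expect_equal(sum(b$level_distribution), 1)
})
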