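test_that("tokenize lowercases, keeps numerals and internal hyphens/decimals", {
  expect_identical(tokenize("Change the dressing after 48 hours.")$tokens,
                   c("change", "the", "dressing", "after", "48", "hours"))
  expect_identical(tokenize("")$tokens, character(0))
  expect_identical(tokenize("Pain-free by day 3.5?")$tokens,
                   c("pain-free", "by", "day", "3.5"))
})

test_that("tokenize matches a character-class brute-force splitter", {
  texts <- c("Take 2.5 mg daily, with food!",
             "Post-op day 3: walk 10 minutes.",
             "Dr. Smith said: rest; then walk (slowly).",
             "A  double  spaced   sentence.",
             "don't over-exert")
  for (tx in texts) {
    expect_identical(tokenize(tx)$tokens, oracle_tokenize(tx), label = tx)
  }
})

test_that("token spans reproduce the matched substrings", {
  tx <- "Change the dressing after 48 hours. Pain-free by 3.5!"
  ts <- tokenize(tx)
  expect_identical(tolower(substring(tx, ts$start, ts$end - 1L)), ts$tokens)
  expect_true(all(diff(ts$start) > 0))
  expect_true(all(ts$end[-length(ts$end)] <= ts$start[-1]))
})

test_that("split_sentences handles boundaries, decimals and abbreviations", {
  expect_length(split_sentences("Rest today. Walk tomorrow.")$sentences, 2L)
  expect_length(split_sentences("Take 2.5 mg daily.")$sentences, 1L)
  para <- paste("Rest fully today.",
                "Some wounds (e.g. small ones) heal fast.",
                "Walk a little tomorrow.",
                "Dr. Smith will see you.",
                "Call us after 48 hours.")
  expect_length(split_sentences(para)$sentences, 5L)
})

test_that("sentence spans cover all non-whitespace text with no empties", {
  texts <- c("One. Two! Three?", "No terminal punctuation",
             "  Leading spaces. And more.  ",
             "Multi\n\nparagraph text. Second sentence here.")
  for (tx in texts) {
    sl <- split_sentences(tx)
    expect_true(all(nzchar(sl$sentences)), label = tx)
    covered <- unlist(mapply(seq, sl$start, sl$end - 1L, SIMPLIFY = FALSE))
    chars <- strsplit(tx, "")[[1]]
    non_ws <- which(grepl("[^[:space:]]", chars))
    expect_true(all(non_ws %in% covered), label = tx)
  }
})

test_that("tokenize and split_sentences are pure (byte-identical reruns)", {
  tx <- "Rest today. Walk 2.5 km tomorrow, Dr. Jones said."
  expect_identical(tokenize(tx), tokenize(tx))
  expect_identical(split_sentences(tx), split_sentences(tx))
})

test_that("fuzzy_jaccard identity, disjoint and degenerate limits", {
  expect_equal(as.numeric(fuzzy_jaccard(c("wound", "care", "daily"),
                                        c("wound", "care", "daily"))), 1)
  expect_equal(as.numeric(fuzzy_jaccard(c("wound", "care"),
                                        c("flight", "booking"), 0.9)), 0)
  deg <- fuzzy_jaccard(character(0), character(0))
  expect_equal(as.numeric(deg), 1)
  expect_true(isTRUE(attr(deg, "degenerate")))
  expect_equal(fuzzy_jaccard(character(0), c("a")), 0)
})

test_that("fuzzy_jaccard matches the exhaustive pairing oracle", {
  expect_equal(fuzzy_jaccard(c("dressing", "change", "48"),
                             c("dressings", "change", "48", "hours"), 0.8),
               oracle_fuzzy_jaccard(c("dressing", "change", "48"),
                                    c("dressings", "change", "48", "hours"),
                                    0.8))
  expect_equal(oracle_fuzzy_jaccard(c("dressing", "change", "48"),
                                    c("dressings", "change", "48", "hours"),
                                    0.8), 0.75)
  set.seed(11)
  vocab <- c("wound", "wounds", "care", "cares", "drain", "drains",
             "walk", "walking", "rest", "rests", "pain", "pains")
  for (rep in 1:25) {
    a <- sample(vocab, sample(1:5, 1))
    b <- sample(vocab, sample(1:5, 1))
    thr <- sample(c(0.6, 0.8, 0.85, 1), 1)
    expect_equal(as.numeric(fuzzy_jaccard(a, b, thr)),
                 oracle_fuzzy_jaccard(a, b, thr),
                 label = paste(thr, paste(a, collapse = "+"),
                               paste(b, collapse = "+")))
  }
})

test_that("fuzzy_jaccard at threshold 1 equals exact set Jaccard", {
  set.seed(7)
  vocab <- letters
  for (rep in 1:30) {
    a <- sample(vocab, sample(1:8, 1))
    b <- sample(vocab, sample(1:8, 1))
    exact <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(as.numeric(fuzzy_jaccard(a, b, 1)), exact)
  }
})

test_that("fuzzy_jaccard stays within [0, 1] and is 1 on self", {
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(c("alpha", "beta", "gamma", "delta", "48", "3.5"),
                sample(1:4, 1))
    b <- sample(c("alpha", "beat", "gamm", "omega"), sample(1:4, 1))
    thr <- runif(1)
    v <- as.numeric(fuzzy_jaccard(a, b, thr))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(as.numeric(fuzzy_jaccard(a, a, thr)), 1)
  }
})
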