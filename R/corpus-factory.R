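# Deterministic synthetic-data factory: the 20-topic knowledge base, the
# 750-query test corpus (250 base queries x 3 variants, category totals
# 600/120/30 as a hard construction constraint, never sampled), gold
# reference answers tied to knowledge-base sentences, and a simulated
# three-reviewer rating set with a configurable agreement structure.

.safety_net_sentence <- "If you have questions or concerns, contact your surgical team."

#' Generate the synthetic knowledge base
#'
#' 20 documents, one per recovery topic, each assembled from authored
#' topic-fact sentences with explicit numerals (timings, doses, limits) so
#' the numeric-fabrication gate is exercised. Content is a fixed authored
#' corpus — byte-identical for any seed; the seed is threaded through for
#' interface symmetry with the other generators.
#'
#' @param seed Integer seed (unused by the fixed content; kept for the
#'   generator contract).
#' @return List of 20 `source_document`s, each at least 1,100 characters.
#' @export
generate_kb <- function(seed = 1L) {
  specs <- kb_topic_specs()
  docs <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    intro <- paste0("This patient handout answers common questions about ",
                    tolower(sp$name),
                    " during recovery at home after surgery.")
    closing <- paste("If anything in this handout is unclear, or your",
                     "situation does not match it, contact your surgical",
                     "team for advice.")
    facts <- vapply(sp$items, `[[`, "", "f")
    body <- paste(c(intro, facts, closing), collapse = " ")
    if (nchar(body) < 1100) {
      stop("knowledge-base document below length budget: ", sp$name)
    }
    new_source_document(doc_id = sprintf("kb-%02d", i), topic = sp$name,
                        title = sp$name, body = body)
  })
  docs
}

lcfirst <- function(s) paste0(tolower(substr(s, 1, 1)), substring(s, 2))

apply_word_map <- function(text, map) {
  for (k in names(map)) {
    text <- gsub(paste0("\\b", k, "\\b"), map[[k]], text, ignore.case = TRUE)
  }
  text
}

# Synonym maps for paraphrasing. Keys are chosen so that no replacement can
# create or destroy a red-flag phrase or introduce medical / topic
# vocabulary into a non-medical query.
.synonyms_a <- c("after" = "following", "start" = "begin",
                 "okay" = "alright", "house" = "place", "best" = "ideal")
.synonyms_b <- c("when can i" = "how soon can i",
                 "should i" = "am i supposed to",
                 "how do i" = "what is the way to",
                 "can i" = "is it alright if i")

paraphrase_variants <- function(base_text, rng_draws) {
  f1 <- c("Hi - %s", "Hello - %s")[rng_draws[1]]
  f2 <- c("Please advise: %s", "I was wondering - %s")[rng_draws[2]]
  v1 <- sprintf(f1, apply_word_map(base_text, .synonyms_a))
  v2 <- sprintf(f2, lcfirst(apply_word_map(base_text, .synonyms_b)))
  c(v1, v2)
}

#' Generate the labeled synthetic test corpus
#'
#' 250 base queries — 200 in-scope (10 per knowledge-base topic), 40
#' out-of-scope non-medical, 10 emergency escalation — each with two
#' rule-based paraphrase variants (register-shift framing plus synonym
#' substitution), for 600/120/30 = 750 queries in total. Every in-scope
#' record carries a `gold_passage` (a sentence present verbatim in the
#' knowledge base) and a `gold_reference` answer. Paraphrasing is
#' label-blind, so category and topic are preserved by construction.
#'
#' @param seed Integer seed driving the paraphrase-frame draws.
#' @return data.frame of query records: `query_id`, `base_id`, `variant`,
#'   `category`, `topic`, `text`, `gold_reference`, `gold_passage`.
#' @export
generate_corpus <- function(seed = 1L) {
  specs <- kb_topic_specs()
  bases <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    stopifnot(length(sp$items) == 10L)
    for (j in seq_along(sp$items)) {
      itm <- sp$items[[j]]
      bases[[length(bases) + 1L]] <- list(
        base_id = sprintf("INS-%02d-%02d", i, j),
        category = "in_scope", topic = sp$name, text = itm$q,
        gold_passage = itm$f,
        gold_reference = paste(itm$f, .safety_net_sentence))
    }
  }
  oos <- oos_base_queries()
  stopifnot(length(oos) == 40L)
  for (j in seq_along(oos)) {
    bases[[length(bases) + 1L]] <- list(
      base_id = sprintf("OOS-%02d", j), category = "out_of_scope",
      topic = NA_character_, text = oos[j],
      gold_passage = NA_character_, gold_reference = NA_character_)
  }
  esc <- escalation_base_queries()
  stopifnot(length(esc) == 10L)
  for (j in seq_along(esc)) {
    bases[[length(bases) + 1L]] <- list(
      base_id = sprintf("ESC-%02d", j), category = "escalation",
      topic = NA_character_, text = esc[j],
      gold_passage = NA_character_, gold_reference = NA_character_)
  }
  stopifnot(length(bases) == 250L)
  draws <- with_preserved_rng({
    set.seed(as.integer(seed) %% 2147483647L)
    matrix(sample.int(2L, size = 2L * length(bases), replace = TRUE),
           ncol = 2L)
  })
  rows <- vector("list", 3L * length(bases))
  n <- 0L
  for (b in seq_along(bases)) {
    base <- bases[[b]]
    variants <- c(base$text, paraphrase_variants(base$text, draws[b, ]))
    for (v in 0:2) {
      n <- n + 1L
      rows[[n]] <- data.frame(
        query_id = sprintf("%s-v%d", base$base_id, v),
        base_id = base$base_id, variant = v,
        category = base$category, topic = base$topic,
        text = variants[v + 1L],
        gold_reference = base$gold_reference,
        gold_passage = base$gold_passage,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate three blinded reviewer ratings for the base queries
#'
#' Emulates the structure of a physician review: a per-item consensus truth
#' (`p_correct`), unanimous agreement except for a configured fraction of
#' 2-vs-1 splits (`split_rate`), and Likert/SSI scores drawn from truncated
#' discrete distributions around configured means. Values are simulated —
#' the reliability coefficients computed downstream characterize the
#' simulator, not any published review.
#'
#' @param corpus Corpus data.frame from [generate_corpus()] (base queries,
#'   variant 0, are rated).
#' @param profile Agreement profile list: `p_correct`, `split_rate`,
#'   `completeness_probs`, `consistency_probs`, `ssi_probs` (defaults from
#'   [default_config()]).
#' @param seed Integer seed.
#' @return data.frame of rating records: `query_id`, `reviewer_id`,
#'   `correct`, `completeness`, `consistency`, `ssi`.
#' @export
simulate_ratings <- function(corpus, profile = default_config()$ratings,
                             seed = 1L) {
  base <- corpus[corpus$variant == 0L, , drop = FALSE]
  reviewers <- c("R1", "R2", "R3")
  with_preserved_rng({
    set.seed((as.integer(seed) + 7L) %% 2147483647L)
    rows <- vector("list", nrow(base))
    for (i in seq_len(nrow(base))) {
      truth <- stats::rbinom(1, 1, profile$p_correct)
      labels <- rep(truth, 3L)
      if (stats::runif(1) < profile$split_rate) {
        flip <- sample.int(3L, 1L)
        labels[flip] <- 1L - labels[flip]
      }
      rows[[i]] <- data.frame(
        query_id = base$query_id[i], reviewer_id = reviewers,
        correct = labels,
        completeness = sample(1:5, 3L, replace = TRUE,
                              prob = profile$completeness_probs),
        consistency = sample(1:5, 3L, replace = TRUE,
                             prob = profile$consistency_probs),
        ssi = sample(0:3, 3L, replace = TRUE, prob = profile$ssi_probs),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write corpus or ratings records as JSON-lines
#'
#' @param records A data.frame.
#' @param path Output `.jsonl` path.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  do.call(rbind, lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
}
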