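# Answer generation under gates: augmented prompt construction, a pluggable
# generator (deterministic extractive default), sentence-level grounding
# verification, and a numeric-fabrication heuristic. A gate failure always
# yields a safe handoff template — the pipeline never returns silence.

#' Build the augmented prompt
#'
#' Deterministic rendering of the fixed role instruction, the question, and
#' the evidence passages (each tagged with its chunk id) in fused-score
#' order. If the rendered prompt exceeds `context_budget` characters,
#' evidence is truncated from the lowest rank upward and the prompt is
#' flagged.
#'
#' @param question Query text.
#' @param evidence An `evidence_set` from [retrieve()] with >= 1 candidate.
#' @param config Configuration list (uses `generation$role_instruction` and
#'   `generation$context_budget`).
#' @return An `augmented_prompt`: fields plus the `rendered` string.
#' @export
build_prompt <- function(question, evidence, config = default_config()) {
  stopifnot(inherits(evidence, "evidence_set"))
  cand <- evidence$candidates
  if (is.null(cand) || !nrow(cand)) stop("evidence set has no candidates")
  role <- config$generation$role_instruction
  budget <- config$generation$context_budget
  render <- function(k) {
    ev <- cand[seq_len(k), , drop = FALSE]
    paste0(role, "\n\nQuestion: ", question, "\n\n",
           paste(sprintf("Evidence [%s]: %s", ev$chunk_id, ev$text),
                 collapse = "\n\n"))
  }
  k <- nrow(cand)
  truncated <- FALSE
  rendered <- render(k)
  while (nchar(rendered) > budget && k > 1L) {
    k <- k - 1L
    truncated <- TRUE
    rendered <- render(k)
  }
  structure(list(role_instruction = role, question = question,
                 evidence = cand[seq_len(k), , drop = FALSE],
                 rendered = rendered, truncated = truncated),
            class = "augmented_prompt")
}

#' @export
print.augmented_prompt <- function(x, ...) {
  cat("<augmented_prompt> ", nchar(x$rendered), " chars, ",
      nrow(x$evidence), " evidence passages\n", sep = "")
  invisible(x)
}

#' Deterministic extractive generator
#'
#' The default generator contract: score every evidence sentence by fuzzy
#' Jaccard against the question, keep those above `floor`, take the
#' `max_sentences` best, and emit them in evidence-rank-then-position order
#' as connected prose. Output sentences are by construction a subset of the
#' evidence sentences. Any hosted LLM adapter can replace this behind the
#' same text-in/text-out contract.
#'
#' @param max_sentences Maximum sentences in a draft (default 5).
#' @param floor Minimum question-similarity for a sentence to be eligible
#'   (default 0.05).
#' @param match_threshold Fuzzy token tolerance (default 0.85).
#' @return A generator handle (a function `augmented_prompt -> draft text`).
#' @export
extractive_generator <- function(max_sentences = 5L, floor = 0.05,
                                 match_threshold = 0.85) {
  force(max_sentences); force(floor); force(match_threshold)
  structure(function(prompt) {
    stopifnot(inherits(prompt, "augmented_prompt"))
    qt <- tokenize(prompt$question)$tokens
    rows <- list()
    for (r in seq_len(nrow(prompt$evidence))) {
      sl <- split_sentences(prompt$evidence$text[r])
      for (p in seq_along(sl$sentences)) {
        s <- sl$sentences[p]
        rows[[length(rows) + 1L]] <- list(
          rank = r, pos = p, sentence = s,
          score = as.numeric(fuzzy_jaccard(qt, tokenize(s)$tokens,
                                           match_threshold)))
      }
    }
    if (!length(rows)) return("")
    score <- vapply(rows, `[[`, numeric(1), "score")
    rank <- vapply(rows, `[[`, numeric(1), "rank")
    pos <- vapply(rows, `[[`, numeric(1), "pos")
    keep <- which(score >= floor)
    if (!length(keep)) return("")
    keep <- keep[order(-score[keep], rank[keep], pos[keep])]
    keep <- utils::head(keep, max_sentences)
    keep <- keep[order(rank[keep], pos[keep])]
    paste(vapply(rows[keep], `[[`, "", "sentence"), collapse = " ")
  }, class = c("extractive_generator", "function"))
}

#' Generate a draft answer from a prompt
#'
#' @param prompt An `augmented_prompt`.
#' @param generator A generator handle (default [extractive_generator()]).
#' @return Draft text; empty string when no evidence sentence is eligible
#'   (triggers the fallback handoff downstream).
#' @export
generate_draft <- function(prompt, generator = extractive_generator()) {
  generator(prompt)
}

evidence_sentences <- function(evidence) {
  unlist(lapply(evidence$candidates$text,
                function(t) split_sentences(t)$sentences),
         use.names = FALSE)
}

#' Sentence-level grounding verification
#'
#' Every draft sentence is scored as the maximum fuzzy Jaccard against the
#' sentences of the evidence passages (the sentence is the grounding unit).
#' The draft is accepted only if ALL sentences reach `threshold`.
#'
#' @param draft Draft answer text (non-empty).
#' @param evidence An `evidence_set`.
#' @param threshold Grounding confidence threshold (default 0.35).
#' @param match_threshold Fuzzy token tolerance (default 0.85).
#' @return List: `scores` (per draft sentence), `accepted`, `failing`
#'   (the sentences below threshold).
#' @export
grounding_verify <- function(draft, evidence, threshold = 0.35,
                             match_threshold = 0.85) {
  stopifnot(nzchar(draft))
  ds <- split_sentences(draft)$sentences
  es <- evidence_sentences(evidence)
  es_tokens <- lapply(es, function(s) tokenize(s)$tokens)
  scores <- vapply(ds, function(s) {
    st <- tokenize(s)$tokens
    if (!length(es_tokens)) return(0)
    max(vapply(es_tokens, function(et) {
      as.numeric(fuzzy_jaccard(st, et, match_threshold))
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  list(scores = scores, accepted = all(scores >= threshold),
       failing = ds[scores < threshold])
}

# Numeral extraction with unit-preserving literal normalization: commas
# stripped, trailing fractional zeros removed ("2.50" -> "2.5"). No unit
# conversion — "2 weeks" and "14 days" deliberately do NOT match.
extract_numerals <- function(text, number_words = FALSE) {
  vals <- regmatches(text, gregexpr("[0-9][0-9,]*(\\.[0-9]+)?", text))[[1]]
  vals <- gsub(",", "", vals)
  has_dot <- grepl("\\.", vals)
  vals[has_dot] <- sub("\\.?0*$", "", sub("(\\.[0-9]*?)0+$", "\\1", vals[has_dot]))
  vals[has_dot] <- sub("\\.$", "", vals[has_dot])
  if (number_words) {
    words <- c(one = "1", two = "2", three = "3", four = "4", five = "5",
               six = "6", seven = "7", eight = "8", nine = "9", ten = "10")
    toks <- tokenize(text)$tokens
    vals <- c(vals, unname(words[toks[toks %in% names(words)]]))
  }
  unique(vals)
}

#' Heuristic validation: fabricated numerals and unsupported references
#'
#' Every numeral in the draft must occur as a numeral in at least one
#' evidence passage (after literal normalization). Citation-like patterns
#' (bracketed numbers, `"et al."`) with no evidence counterpart are also
#' flagged. Accept iff no flags.
#'
#' @param draft Draft text (non-empty).
#' @param evidence An `evidence_set`.
#' @param number_words Also map the words one..ten to numerals.
#' @return List: `numeric_flags` (unsupported numerals/citations),
#'   `accepted`.
#' @export
heuristic_validate <- function(draft, evidence, number_words = FALSE) {
  stopifnot(nzchar(draft))
  ev_text <- paste(evidence$candidates$text, collapse = " ")
  dn <- extract_numerals(draft, number_words)
  en <- extract_numerals(ev_text, number_words)
  flags <- setdiff(dn, en)
  cite <- c("\\[[0-9]+\\]", "et al\\.")
  for (p in cite) {
    if (grepl(p, draft) && !grepl(p, ev_text)) {
      flags <- c(flags, paste0("citation:", p))
    }
  }
  list(numeric_flags = flags, accepted = !length(flags))
}

new_verified_answer <- function(query_id, query, status, text,
                                sentence_scores = numeric(0),
                                numeric_flags = character(0),
                                evidence_ids = character(0),
                                trace = NULL, trigger = character(0)) {
  structure(list(query_id = query_id, query = query, status = status,
                 text = text, sentence_scores = sentence_scores,
                 numeric_flags = numeric_flags, evidence_ids = evidence_ids,
                 trace = trace, trigger = trigger),
            class = "verified_answer")
}

#' @export
print.verified_answer <- function(x, ...) {
  cat("<verified_answer> [", x$status, "] ",
      substr(x$text, 1, 70), if (nchar(x$text) > 70) "...", "\n", sep = "")
  invisible(x)
}

#' Answer a query end-to-end (safety route, retrieve, generate, gate)
#'
#' Orchestration: the safety router runs first (escalation and out-of-scope
#' short-circuit with their predefined templates, no generation attempted);
#' otherwise retrieve -> prompt -> draft -> grounding gate -> heuristic
#' gate. Any gate failure yields the configured safe fallback text, never
#' silence: the function always returns a `verified_answer` (0% no-response
#' contract). `status = "delivered"` guarantees every sentence score is at
#' or above the grounding threshold and no numeric flag was raised.
#'
#' @param query Patient query text.
#' @param kb A [build_kb()] handle.
#' @param config Configuration (defaults to the kb config).
#' @param query_id Optional id recorded in the answer.
#' @param generator Generator handle (default [extractive_generator()] built
#'   from the config).
#' @return A `verified_answer` with status one of `delivered`,
#'   `rejected_grounding`, `rejected_heuristic`, `declined_scope`,
#'   `escalated`, `fallback_handoff`.
#' @export
answer_query <- function(query, kb, config = NULL, query_id = NA_character_,
                         generator = NULL) {
  config <- config %||% kb$config
  generator <- generator %||% extractive_generator(
    max_sentences = config$generation$max_sentences,
    floor = config$generation$selection_floor,
    match_threshold = config$grounding$match_threshold)
  decision <- route_query(query, kb, config)
  if (decision$route == "escalate") {
    return(new_verified_answer(query_id, query, "escalated",
                               config$templates$escalation,
                               trigger = decision$trigger))
  }
  if (decision$route == "decline_out_of_scope") {
    return(new_verified_answer(query_id, query, "declined_scope",
                               config$templates$decline,
                               trigger = decision$trigger))
  }
  res <- tryCatch({
    ev <- retrieve(query, kb,
                   k_ann = config$retrieval$k_ann,
                   k_final = config$retrieval$k_final,
                   alpha = config$retrieval$alpha)
    if (isTRUE(ev$zero_information) || is.null(ev$candidates) ||
        !nrow(ev$candidates)) {
      return(new_verified_answer(query_id, query, "fallback_handoff",
                                 config$templates$fallback))
    }
    prompt <- build_prompt(query, ev, config)
    draft <- generate_draft(prompt, generator)
    ids <- ev$candidates$chunk_id
    if (!nzchar(draft)) {
      return(new_verified_answer(query_id, query, "fallback_handoff",
                                 config$templates$fallback,
                                 evidence_ids = ids, trace = ev$trace))
    }
    g <- grounding_verify(draft, ev,
                          threshold = config$grounding$threshold,
                          match_threshold = config$grounding$match_threshold)
    if (!g$accepted) {
      return(new_verified_answer(query_id, query, "rejected_grounding",
                                 config$templates$fallback,
                                 sentence_scores = g$scores,
                                 evidence_ids = ids, trace = ev$trace))
    }
    h <- heuristic_validate(draft, ev,
                            number_words = config$heuristic$number_words)
    if (!h$accepted) {
      return(new_verified_answer(query_id, query, "rejected_heuristic",
                                 config$templates$fallback,
                                 sentence_scores = g$scores,
                                 numeric_flags = h$numeric_flags,
                                 evidence_ids = ids, trace = ev$trace))
    }
    new_verified_answer(query_id, query, "delivered", draft,
                        sentence_scores = g$scores,
                        evidence_ids = ids, trace = ev$trace)
  }, error = function(e) {
    new_verified_answer(query_id, query, "fallback_handoff",
                        config$templates$fallback,
                        trigger = paste0("error:", conditionMessage(e)))
  })
  res
}
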