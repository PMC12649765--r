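# Safety routing: every query is classified BEFORE any generation as
# answerable, out-of-scope (non-medical), or an emergency escalation.
# Escalation detection is lexicon/pattern based (a safety gate must be
# deterministic and reviewable); out-of-scope detection combines two
# independent signals: low retrieval affinity against the knowledge base AND
# absence of medical-domain vocabulary. Escalation takes precedence.

#' Red-flag symptom lexicon
#'
#' Phrases describing postoperative emergencies (breathing difficulty,
#' uncontrolled bleeding, chest pain, high fever, loss of consciousness,
#' spreading infection signs, calf swelling). Matching is phrase-level over
#' tokens with fuzzy tolerance, so minor inflection does not defeat the
#' gate. Names give the trigger category.
#'
#' @return Named character vector: `names` are categories, values phrases.
#' @export
red_flag_lexicon <- function() {
  c(breathing_difficulty = "trouble breathing",
    breathing_difficulty = "can't breathe",
    breathing_difficulty = "cannot breathe",
    breathing_difficulty = "short of breath",
    breathing_difficulty = "shortness of breath",
    breathing_difficulty = "difficulty breathing",
    breathing_difficulty = "can't catch my breath",
    breathing_difficulty = "dyspnea",
    uncontrolled_bleeding = "bleeding won't stop",
    uncontrolled_bleeding = "won't stop bleeding",
    uncontrolled_bleeding = "soaking through",
    uncontrolled_bleeding = "blood soaking",
    uncontrolled_bleeding = "bleeding heavily",
    uncontrolled_bleeding = "uncontrolled bleeding",
    uncontrolled_bleeding = "gushing blood",
    chest_pain = "chest pain",
    chest_pain = "pain in my chest",
    chest_pain = "pressure in my chest",
    chest_pain = "chest feels tight",
    high_fever = "high fever",
    high_fever = "fever of 103",
    high_fever = "fever over 101",
    high_fever = "temperature above 101",
    high_fever = "temperature is 103",
    loss_of_consciousness = "passed out",
    loss_of_consciousness = "fainted",
    loss_of_consciousness = "unconscious",
    loss_of_consciousness = "losing consciousness",
    loss_of_consciousness = "blacked out",
    loss_of_consciousness = "hard to wake",
    spreading_infection = "red streaks",
    spreading_infection = "spreading redness",
    spreading_infection = "foul-smelling drainage",
    spreading_infection = "pus pouring",
    calf_swelling = "calf is swollen",
    calf_swelling = "calf swelling",
    calf_swelling = "swollen and painful calf",
    calf_swelling = "calf pain and swelling")
}

#' Medical-domain token lexicon
#'
#' Tokens whose (fuzzy) presence marks a query as medically oriented; used
#' as the second, independent signal of the out-of-scope detector. A query
#' is declined only when it BOTH scores below the retrieval-affinity floor
#' and contains none of these tokens — the conjunction biases the router
#' toward answering medical queries.
#'
#' @return Character vector of tokens.
#' @export
medical_lexicon <- function() {
  c("surgery", "surgical", "surgeon", "operation", "postoperative",
    "post-op", "incision", "wound", "dressing", "bandage", "drain",
    "suture", "sutures", "stitches", "staples", "scar", "scars",
    "swelling", "bruising", "pain", "painful", "medication", "medications",
    "medicine", "nausea", "vomiting", "recovery", "recovering", "healing",
    "heal", "doctor", "nurse", "clinic", "hospital", "anesthesia",
    "prescription", "pills", "acetaminophen", "ibuprofen", "opioid",
    "garment", "compression", "appointment", "follow-up", "discharge",
    "symptom", "symptoms", "fever", "infection", "bleeding", "numbness")
}

# Small English stopword list used only for scope-affinity scoring: the
# hashed bag-of-tokens embedding would otherwise let function words give
# every query a non-trivial cosine against every chunk.
scope_stopwords <- function() {
  c("a", "an", "the", "i", "me", "my", "we", "our", "you", "your", "it",
    "its", "is", "am", "are", "was", "were", "be", "been", "do", "does",
    "did", "can", "could", "should", "would", "will", "shall", "may",
    "might", "have", "has", "had", "to", "of", "in", "on", "at", "for",
    "with", "and", "or", "but", "if", "when", "how", "what", "which",
    "who", "where", "why", "this", "that", "these", "those", "there",
    "from", "by", "as", "about", "after", "before", "so", "not", "no",
    "t", "s", "don", "won", "isn", "they", "them", "their", "he", "she",
    "up", "down", "out", "off", "back", "again", "still", "also", "very",
    "some", "any", "more", "most", "other", "such", "than", "then", "too")
}

match_phrase <- function(query_tokens, phrase_tokens, match_threshold) {
  np <- length(phrase_tokens)
  nq <- length(query_tokens)
  if (np == 0L || nq < np) return(FALSE)
  S <- token_similarity(query_tokens, phrase_tokens)
  for (i in seq_len(nq - np + 1L)) {
    if (all(S[cbind(i:(i + np - 1L), seq_len(np))] >= match_threshold)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Detect emergency escalation in a query
#'
#' @param query Query text.
#' @param lexicon Named phrase vector, default [red_flag_lexicon()].
#' @param match_threshold Per-token fuzzy tolerance (default 0.85).
#' @return List: `escalate` (logical), `triggers` (matched categories).
#' @export
detect_escalation <- function(query, lexicon = red_flag_lexicon(),
                              match_threshold = 0.85) {
  qt <- tokenize(query)$tokens
  hit <- vapply(lexicon, function(p) {
    match_phrase(qt, tokenize(p)$tokens, match_threshold)
  }, logical(1))
  list(escalate = any(hit), triggers = unique(names(lexicon)[hit]))
}

# Scope affinity = number of informative query tokens that (fuzzily) occur
# together in some single knowledge-base chunk. A query token is
# informative when it is not a stopword and does not merely match
# ubiquitous vocabulary (tokens present in more than `df_cut` of chunks
# carry no scope information in this corpus). Counting within one chunk,
# rather than across the whole base, is what separates a topically anchored
# question from a query that shares only scattered everyday words.
scope_affinity <- function(query, kb, df_cut = NULL) {
  df_cut <- df_cut %||% kb$config$safety$df_cut %||% 0.4
  sc <- kb$scope
  qt <- unique(tokenize(query)$tokens)
  qt <- qt[!qt %in% scope_stopwords()]
  if (!length(qt)) return(0)
  S <- token_similarity(qt, sc$vocab)
  matched <- lapply(seq_along(qt), function(i) which(S[i, ] >= 0.85))
  keep <- which(vapply(matched, function(m) {
    length(m) > 0 && min(sc$df_fraction[m]) <= df_cut
  }, logical(1)))
  if (!length(keep)) return(0)
  best <- 0L
  for (cs in sc$chunk_sets) {
    hits <- sum(vapply(keep, function(i) any(matched[[i]] %in% cs),
                       logical(1)))
    if (hits > best) best <- hits
  }
  as.numeric(best)
}

# per-chunk vocabulary statistics backing scope_affinity; computed once at
# knowledge-base build time
scope_statistics <- function(chunks) {
  chunk_toks <- lapply(chunks$text, function(t) unique(tokenize(t)$tokens))
  vocab <- sort(unique(unlist(chunk_toks)))
  member <- vapply(chunk_toks, function(ct) vocab %in% ct,
                   logical(length(vocab)))
  list(vocab = vocab,
       df_fraction = rowMeans(member),
       chunk_sets = lapply(chunk_toks, match, table = vocab))
}

#' Detect an out-of-scope (non-medical) query
#'
#' Out-of-scope iff the scope affinity — the largest number of informative
#' query tokens co-occurring (fuzzily) in a single knowledge-base chunk —
#' falls below `scope_floor` AND no medical-lexicon token is (fuzzily)
#' present. The floor default was calibrated once as the 5th percentile of
#' in-scope affinities on the synthetic corpus ([calibrate_scope_floor()]).
#'
#' @param query Query text.
#' @param kb A [build_kb()] handle.
#' @param scope_floor Affinity floor; `NULL` uses the kb config.
#' @param match_threshold Fuzzy tolerance for lexicon tokens.
#' @return List: `out_of_scope`, `score` (best affinity), `medical_hit`.
#' @export
detect_out_of_scope <- function(query, kb, scope_floor = NULL,
                                match_threshold = 0.85) {
  floor_v <- scope_floor %||% kb$config$safety$scope_floor
  score <- scope_affinity(query, kb)
  qt <- unique(tokenize(query)$tokens)
  med <- FALSE
  if (length(qt)) {
    S <- token_similarity(qt, medical_lexicon())
    med <- any(S >= match_threshold)
  }
  list(out_of_scope = (score < floor_v) && !med,
       score = score, medical_hit = med)
}

#' Route a query through the safety gates
#'
#' Precedence: escalate > decline_out_of_scope > answer. Deterministic; the
#' query and knowledge base are never mutated.
#'
#' @param query Query text.
#' @param kb A [build_kb()] handle.
#' @param config Configuration; defaults to the kb config.
#' @return A `safety_decision`: `route`, `trigger`, `template_id`.
#' @export
route_query <- function(query, kb, config = NULL) {
  config <- config %||% kb$config
  esc <- detect_escalation(query,
                           match_threshold = config$safety$match_threshold)
  if (esc$escalate) {
    return(structure(list(route = "escalate", trigger = esc$triggers,
                          template_id = "escalation"),
                     class = "safety_decision"))
  }
  oos <- detect_out_of_scope(query, kb,
                             scope_floor = config$safety$scope_floor,
                             match_threshold = config$safety$match_threshold)
  if (oos$out_of_scope) {
    return(structure(list(route = "decline_out_of_scope",
                          trigger = sprintf("affinity=%.3f", oos$score),
                          template_id = "decline"),
                     class = "safety_decision"))
  }
  structure(list(route = "answer", trigger = character(0),
                 template_id = NA_character_),
            class = "safety_decision")
}

#' @export
print.safety_decision <- function(x, ...) {
  cat("<safety_decision> ", x$route,
      if (length(x$trigger)) paste0(" [", paste(x$trigger, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Calibrate the out-of-scope affinity floor
#'
#' The data-driven default: the 5th percentile of the scope affinities of a
#' set of known in-scope queries against the knowledge base.
#'
#' @param kb A [build_kb()] handle.
#' @param in_scope_queries Character vector of in-scope query texts.
#' @param probs Quantile to take (default 0.05).
#' @return The calibrated floor (numeric).
#' @export
calibrate_scope_floor <- function(kb, in_scope_queries, probs = 0.05) {
  scores <- vapply(in_scope_queries, scope_affinity, numeric(1), kb = kb,
                   USE.NAMES = FALSE)
  as.numeric(stats::quantile(scores, probs = probs, type = 7))
}
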