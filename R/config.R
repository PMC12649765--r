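# Run configuration: every numeric constant of the pipeline lives here
# (chunk size, embedding dimension, HNSW parameters, retrieval depths,
# grounding threshold, safety lexicons and templates, evaluation settings),
# so a saved config reproduces a run bit-for-bit on the deterministic stack.

#' Default pipeline configuration
#'
#' @param seed Master seed for every stochastic stage (corpus paraphrase
#'   framing, rating simulation, HNSW level assignment, embedding hashes).
#' @return A nested list; see the methods vignette for the meaning, units
#'   and rationale of each entry.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    chunking = list(chunk_limit = 500L, paragraph_break = TRUE,
                    paragraph_fill = 0.6),
    embedding = list(dimension = 768L, seed = seed),
    index = list(M = 32L, ef_construction = 200L, ef_search = 100L,
                 seed = seed),
    retrieval = list(k_ann = 10L, k_final = 3L, alpha = 0.5,
                     k1 = 1.5, b = 0.75),
    generation = list(
      role_instruction = "You are a postoperative-care assistant",
      max_sentences = 5L, selection_floor = 0.05, context_budget = 6000L),
    grounding = list(threshold = 0.35, match_threshold = 0.85),
    heuristic = list(number_words = FALSE),
    safety = list(scope_floor = 2, df_cut = 0.4, match_threshold = 0.85),
    evaluation = list(chunk_words = 300L, k = 4L, mmr_lambda = 0.7,
                      tau_support = 0.35),
    ratings = list(p_correct = 0.98, split_rate = 0.02,
                   completeness_probs = c(0, 0.005, 0.02, 0.115, 0.86),
                   consistency_probs = c(0.01, 0.02, 0.08, 0.25, 0.64),
                   ssi_probs = c(0.01, 0.05, 0.19, 0.75)),
    templates = list(
      escalation = paste(
        "Your symptoms may need urgent medical attention.",
        "Please call your surgical team now or go to the nearest emergency",
        "department. This assistant cannot handle emergencies."),
      decline = paste(
        "I can only help with questions about recovery after surgery.",
        "Please ask about your postoperative care, or contact your care",
        "team for other concerns."),
      fallback = paste(
        "I'm not able to give a reliable, evidence-grounded answer to that",
        "question. Please contact your surgical team for guidance."))
  )
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A configuration list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Stable hash of a configuration
#'
#' Written next to every run output so artifacts can be traced to the exact
#' configuration that produced them.
#'
#' @param config A configuration list.
#' @return An integer hash.
#' @export
config_hash <- function(config) {
  string_hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA)))
}
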