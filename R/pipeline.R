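# End-to-end orchestration: fixtures -> ingest -> index -> route + answer
# -> human-metric report (on simulated ratings) -> automated-metric report.
# Every stage is deterministic under a fixed config, so a rerun from the
# same config reproduces answers, routes and reports byte-for-byte.

status_to_route <- function(status) {
  ifelse(status == "escalated", "escalate",
         ifelse(status == "declined_scope", "decline_out_of_scope", "answer"))
}

answers_to_df <- function(answers) {
  do.call(rbind, lapply(answers, function(a) {
    data.frame(query_id = a$query_id, status = a$status, text = a$text,
               n_sentences = length(a$sentence_scores),
               min_sentence_score = if (length(a$sentence_scores)) {
                 min(a$sentence_scores)
               } else NA_real_,
               n_numeric_flags = length(a$numeric_flags),
               evidence_ids = paste(a$evidence_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

write_answers_jsonl <- function(answers, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (a in answers) {
    rec <- list(query_id = a$query_id, status = a$status, text = a$text,
                sentence_scores = a$sentence_scores,
                numeric_flags = a$numeric_flags,
                evidence_ids = a$evidence_ids)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Batch-answer a query corpus
#'
#' @param corpus Corpus data.frame from [generate_corpus()] (or any
#'   data.frame with `query_id` and `text`).
#' @param kb A [build_kb()] handle.
#' @param config Configuration; defaults to the kb config.
#' @return List of `verified_answer`s, one per corpus row, in corpus order.
#' @export
batch_answer <- function(corpus, kb, config = NULL) {
  config <- config %||% kb$config
  generator <- extractive_generator(
    max_sentences = config$generation$max_sentences,
    floor = config$generation$selection_floor,
    match_threshold = config$grounding$match_threshold)
  lapply(seq_len(nrow(corpus)), function(i) {
    answer_query(corpus$text[i], kb, config,
                 query_id = corpus$query_id[i], generator = generator)
  })
}

#' Human-evaluation metric report for a batch run
#'
#' Consensus labels by majority vote, the micro-averaged confusion matrix
#' (actual positive = in-scope; predicted positive = delivered answer;
#' a true positive additionally requires reviewer-consensus correctness),
#' topic-level accuracy over the 20 topics plus the out-of-scope and
#' escalation domains, Likert/SSI summaries, and the inter-rater
#' reliability suite.
#'
#' @param corpus Corpus data.frame (base queries are evaluated).
#' @param answers List of `verified_answer`s aligned with `corpus` rows.
#' @param ratings Rating records from [simulate_ratings()].
#' @return A `human_report` list.
#' @export
evaluate_human <- function(corpus, answers, ratings) {
  adf <- answers_to_df(answers)
  base <- corpus[corpus$variant == 0L, , drop = FALSE]
  m <- match(base$query_id, adf$query_id)
  stopifnot(!anyNA(m))
  status <- adf$status[m]
  lab <- matrix(ratings$correct, ncol = 3L, byrow = TRUE,
                dimnames = list(NULL, c("R1", "R2", "R3")))
  stopifnot(nrow(lab) == nrow(base))
  cons <- consensus_labels(lab)
  actual_pos <- base$category == "in_scope"
  pred_pos <- status == "delivered"
  tp <- sum(actual_pos & pred_pos & cons == 1L)
  fn <- sum(actual_pos & (!pred_pos | cons == 0L))
  tn <- sum(!actual_pos & !pred_pos)
  fp <- sum(!actual_pos & pred_pos)
  cm <- confusion_matrix(tp, fp, fn, tn)
  cls <- classification_metrics(cm)
  domain <- ifelse(actual_pos, base$topic,
                   ifelse(base$category == "escalation",
                          "Emergency Escalation", "Out-of-Scope"))
  correct_item <- (actual_pos & pred_pos & cons == 1L) |
    (!actual_pos & !pred_pos)
  per_topic <- stats::aggregate(
    cbind(n_correct = correct_item, n_total = rep(1L, length(domain))),
    by = list(topic = domain), FUN = sum)
  topics <- topic_accuracy(per_topic)
  counts <- t(vapply(seq_len(nrow(lab)), function(i) {
    tabulate(lab[i, ] + 1L, nbins = 2L)
  }, integer(2)))
  rel <- list(
    fleiss = fleiss_kappa(counts),
    pairwise_cohen = pairwise_cohen_kappa(lab),
    krippendorff_nominal = krippendorff_alpha(lab, "nominal"),
    icc_completeness = local({
      comp <- matrix(ratings$completeness, ncol = 3L, byrow = TRUE)
      list(single = icc_two_way(comp, "single"),
           average = icc_two_way(comp, "average"))
    }))
  structure(list(
    confusion = cm, classification = cls, topic_accuracy = topics,
    likert = list(completeness = likert_summary(ratings, "completeness"),
                  consistency = likert_summary(ratings, "consistency"),
                  ssi = likert_summary(ratings, "ssi")),
    reliability = rel,
    consensus = data.frame(query_id = base$query_id, consensus = cons,
                           stringsAsFactors = FALSE)),
    class = "human_report")
}

#' Automated metric report for a batch run
#'
#' Groundedness of delivered in-scope answers against evidence retrieved by
#' the two-stage evaluation retriever, fluency of delivered answers against
#' their gold references, and a readability summary over every response
#' text.
#'
#' @param corpus Corpus data.frame.
#' @param answers List of `verified_answer`s aligned with `corpus` rows.
#' @param docs Knowledge-base documents (for the evaluation re-chunking).
#' @param config Configuration list.
#' @return An `auto_report` list.
#' @export
evaluate_auto <- function(corpus, answers, docs, config = default_config()) {
  ekb <- build_eval_kb(docs, config)
  tau <- config$evaluation$tau_support
  mt <- config$grounding$match_threshold
  status <- vapply(answers, `[[`, "", "status")
  text <- vapply(answers, `[[`, "", "text")
  idx <- which(corpus$category == "in_scope" & status == "delivered")
  g_items <- lapply(idx, function(i) {
    retrieved <- eval_retrieve(corpus$text[i], ekb)
    list(answer = text[i], gold_passage = corpus$gold_passage[i],
         retrieved = retrieved$text)
  })
  gr <- if (length(g_items)) {
    groundedness_report(g_items, tau_support = tau, match_threshold = mt)
  }
  backend <- hash_embedding_backend(config$embedding$dimension,
                                    config$embedding$seed)
  fl <- lapply(idx, function(i) {
    fluency(text[match(corpus$query_id[i], vapply(answers, `[[`, "", "query_id"))],
            corpus$gold_reference[i], backend)
  })
  fl_mean <- if (length(fl)) {
    fields <- names(fl[[1]])
    stats::setNames(lapply(fields, function(f) {
      mean(vapply(fl, function(x) as.numeric(x[[f]]), numeric(1)))
    }), fields)
  }
  structure(list(groundedness = gr, fluency = fl_mean,
                 readability = readability_batch(text[nzchar(text)]),
                 n_scored = length(idx)),
            class = "auto_report")
}

#' Run the full pipeline and write a reproducible run directory
#'
#' Executes fixtures -> ingest -> index -> route + answer (750 queries) ->
#' human metrics (simulated ratings) -> automated metrics, then writes
#' `answers.jsonl`, `routes.csv`, `human_report.json`, `auto_report.json`,
#' `config.yaml` and `config_hash.txt` under `out_dir`.
#'
#' @param config A [default_config()] list.
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output.
#' @param stages Character subset of `c("answer", "human", "auto")`;
#'   evaluation stages can be dropped for quick runs.
#' @return Invisibly, a list with `kb`, `corpus`, `answers`, `routes`,
#'   `human`, `auto`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         stages = c("answer", "human", "auto")) {
  docs <- generate_kb(config$seed)
  kb <- build_kb(docs, config)
  corpus <- generate_corpus(config$seed)
  answers <- NULL; routes <- NULL; human <- NULL; auto <- NULL
  if ("answer" %in% stages) {
    answers <- batch_answer(corpus, kb, config)
    routes <- data.frame(
      query_id = corpus$query_id, category = corpus$category,
      route = status_to_route(vapply(answers, `[[`, "", "status")),
      status = vapply(answers, `[[`, "", "status"),
      stringsAsFactors = FALSE)
    if ("human" %in% stages) {
      ratings <- simulate_ratings(corpus, config$ratings, config$seed)
      human <- evaluate_human(corpus, answers, ratings)
    }
    if ("auto" %in% stages) {
      auto <- evaluate_auto(corpus, answers, docs, config)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(as.character(config_hash(config)),
               file.path(out_dir, "config_hash.txt"))
    if (!is.null(answers)) {
      write_answers_jsonl(answers, file.path(out_dir, "answers.jsonl"))
      utils::write.csv(routes, file.path(out_dir, "routes.csv"),
                       row.names = FALSE)
    }
    if (!is.null(human)) {
      jsonlite::write_json(report_to_list(human),
                           file.path(out_dir, "human_report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    if (!is.null(auto)) {
      jsonlite::write_json(report_to_list(auto),
                           file.path(out_dir, "auto_report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  invisible(list(kb = kb, corpus = corpus, answers = answers,
                 routes = routes, human = human, auto = auto))
}

# strip closures/environments so reports serialize cleanly
report_to_list <- function(x) {
  if (is.environment(x) || is.function(x)) return(NULL)
  if (inherits(x, "table")) return(as.list(stats::setNames(as.numeric(x), names(x))))
  if (is.list(x)) {
    out <- lapply(unclass(x), report_to_list)
    return(out[!vapply(out, is.null, logical(1))])
  }
  x
}
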