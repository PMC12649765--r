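Package: ragcare
Title: Grounded Retrieval-Augmented Question Answering for Postoperative
    Patient Education
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale, provider-agnostic implementation of a
    retrieval-augmented generation (RAG) pipeline for grounded postoperative
    patient-education question answering. Ingests patient handouts into
    sentence-respecting ~500-character chunks, indexes deterministic hashed
    bag-of-tokens embeddings in a hierarchical navigable small-world (HNSW)
    approximate nearest-neighbour graph, re-ranks candidates by a hybrid of
    dense cosine similarity and Okapi BM25, and generates extractive answers
    under sentence-level grounding verification and numeric-fabrication
    gates. Queries are first routed through deterministic safety guardrails
    (emergency escalation detection, out-of-scope decline). Ships a
    synthetic knowledge-base and query-corpus factory plus a complete
    evaluation battery: confusion-matrix metrics with Wald and Wilson
    intervals, majority-vote consensus, Fleiss and Cohen kappa,
    Krippendorff alpha, intraclass correlation, fuzzy-Jaccard groundedness
    with a two-stage hybrid evaluation retriever, BLEU/ROUGE fluency, and
    Flesch-Kincaid readability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
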