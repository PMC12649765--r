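# Knowledge-base ingestion: load patient handouts and segment them into
# non-overlapping, sentence-respecting ~500-character chunks (the retrieval
# unit). "Semantically coherent" is operationalized as greedy sentence
# packing: a sentence is never split across chunks, and paragraph breaks can
# force an early boundary once a chunk is mostly full.

new_source_document <- function(doc_id, topic, title, body) {
  stopifnot(nzchar(body))
  structure(list(doc_id = doc_id, topic = topic, title = title, body = body),
            class = "source_document")
}

#' @export
print.source_document <- function(x, ...) {
  cat("<source_document> ", x$doc_id, " [", x$topic, "], ",
      nchar(x$body), " chars\n", sep = "")
  invisible(x)
}

#' Load knowledge-base documents from disk
#'
#' Reads UTF-8 plain-text or Markdown files (one document per file). An
#' optional leading `topic:` header line assigns the topic (otherwise
#' `"unassigned"`); Markdown heading markers are stripped from the body.
#' Empty files are skipped with a warning.
#'
#' @param path A directory of `.txt`/`.md` files, or a single file.
#' @return A list of `source_document` objects.
#' @export
load_documents <- function(path) {
  stopifnot(length(path) == 1L)
  if (!file.exists(path)) stop("path does not exist: ", path)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(txt|md)$", full.names = TRUE)
  } else {
    path
  }
  files <- sort(files)
  if (!length(files)) {
    warning("no documents found under ", path)
    return(list())
  }
  docs <- list()
  for (f in files) {
    lines <- tryCatch(readLines(f, encoding = "UTF-8", warn = FALSE),
                      error = function(e) {
                        stop("unreadable file: ", f, " (", conditionMessage(e), ")")
                      })
    if (!length(lines) || !any(nzchar(trimws(lines)))) {
      warning("skipping empty file: ", f)
      next
    }
    topic <- "unassigned"
    title <- tools::file_path_sans_ext(basename(f))
    if (grepl("^topic:", lines[1], ignore.case = TRUE)) {
      topic <- trimws(sub("^topic:", "", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    }
    if (length(lines) && grepl("^#", lines[1])) {
      title <- trimws(sub("^#+\\s*", "", lines[1]))
      lines <- lines[-1]
    }
    body <- sub("^\\s+", "", paste(sub("^#+\\s*", "", lines), collapse = "\n"))
    body <- sub("\\s+$", "", body)
    if (!nzchar(body)) {
      warning("skipping file with empty body: ", f)
      next
    }
    docs[[length(docs) + 1L]] <- new_source_document(
      doc_id = tools::file_path_sans_ext(basename(f)),
      topic = topic, title = title, body = body)
  }
  ids <- vapply(docs, `[[`, "", "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id among loaded documents")
  docs
}

#' Segment one document into non-overlapping chunks
#'
#' Greedy sentence packing: sentences are appended to the current chunk while
#' the chunk (measured as a contiguous span of the body) stays within
#' `chunk_limit` characters. A single sentence longer than the limit becomes
#' its own chunk, flagged `overflow`. A blank-line paragraph break forces a
#' boundary once the current chunk is at least `paragraph_fill` full (set
#' `paragraph_break = FALSE` to disable). Chunks never split a sentence and
#' have pairwise-disjoint spans covering every sentence of the body.
#'
#' @param doc A `source_document`.
#' @param chunk_limit Target chunk size in characters (default 500, min 100).
#' @param paragraph_break Force a boundary at blank lines when the chunk is
#'   already `paragraph_fill` full.
#' @param paragraph_fill Fullness fraction above which a paragraph break ends
#'   the chunk (default 0.6).
#' @return A data.frame of chunks: `chunk_id`, `doc_id`, `topic`, `text`,
#'   `start`, `end` (offsets into the body, end exclusive), `token_count`,
#'   `overflow`.
#' @export
chunk_document <- function(doc, chunk_limit = 500L, paragraph_break = TRUE,
                           paragraph_fill = 0.6) {
  stopifnot(inherits(doc, "source_document"), chunk_limit >= 100)
  sl <- split_sentences(doc$body)
  ns <- length(sl$sentences)
  if (!ns) stop("document has no sentences: ", doc$doc_id)
  # paragraph break between sentence i and i+1?
  para_after <- logical(ns)
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      gap <- substring(doc$body, sl$end[i], sl$start[i + 1L] - 1L)
      para_after[i] <- grepl("\n[[:blank:]]*\n", gap)
    }
  }
  groups <- list()
  cur <- integer(0)
  cur_start <- NA_integer_
  for (i in seq_len(ns)) {
    if (!length(cur)) {
      cur <- i
      cur_start <- sl$start[i]
    } else if (sl$end[i] - cur_start <= chunk_limit) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
      cur_start <- sl$start[i]
    }
    full <- (sl$end[i] - cur_start) / chunk_limit
    if (paragraph_break && para_after[i] && full >= paragraph_fill) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) groups[[length(groups) + 1L]] <- cur
  out <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    s0 <- sl$start[idx[1]]
    e0 <- sl$end[idx[length(idx)]]
    txt <- substring(doc$body, s0, e0 - 1L)
    data.frame(
      chunk_id = sprintf("%s-c%03d", doc$doc_id, g),
      doc_id = doc$doc_id,
      topic = doc$topic,
      text = txt,
      start = s0,
      end = e0,
      token_count = length(tokenize(txt)$tokens),
      overflow = nchar(txt) > chunk_limit,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chunk a list of documents
#'
#' @param docs List of `source_document` objects.
#' @inheritParams chunk_document
#' @return A single data.frame of chunks across all documents.
#' @export
chunk_documents <- function(docs, chunk_limit = 500L, paragraph_break = TRUE,
                            paragraph_fill = 0.6) {
  stopifnot(length(docs) > 0)
  do.call(rbind, lapply(docs, chunk_document, chunk_limit = chunk_limit,
                        paragraph_break = paragraph_break,
                        paragraph_fill = paragraph_fill))
}

#' Write / read chunks as JSON-lines
#'
#' @param chunks Chunk data.frame from [chunk_documents()].
#' @param path File path for the `.jsonl` output.
#' @return `write_chunks` returns `path` invisibly; `read_chunks` returns the
#'   chunk data.frame.
#' @export
write_chunks <- function(chunks, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(chunks))) {
    writeLines(jsonlite::toJSON(as.list(chunks[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_chunks
#' @export
read_chunks <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
}
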