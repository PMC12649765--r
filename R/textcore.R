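# Deterministic text primitives shared by every other module: tokenization,
# rule-based sentence segmentation, normalized edit-distance similarity and
# the fuzzy-Jaccard set overlap that underlies grounding and groundedness.

`%||%` <- function(x, y) if (is.null(x)) y else x

new_token_sequence <- function(tokens, start, end, text) {
  structure(list(tokens = tokens, start = start, end = end, text = text),
            class = "token_sequence")
}

#' Tokenize text into lowercased word tokens
#'
#' Splits on non-alphanumeric boundaries while keeping decimal points and
#' internal hyphens inside a token, so `"3.5"` and `"pain-free"` survive as
#' single tokens. Pure and deterministic; empty input yields an empty
#' sequence.
#'
#' @param text A length-one character string.
#' @return A `token_sequence`: lowercased `tokens` plus character offsets
#'   (`start` 1-based, `end` exclusive) into the original text.
#' @examples
#' tokenize("Change the dressing after 48 hours.")$tokens
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(new_token_sequence(character(0), integer(0), integer(0), ""))
  }
  m <- gregexpr("[[:alnum:]]+([.-][[:alnum:]]+)*", text)[[1]]
  if (m[1] == -1L) {
    return(new_token_sequence(character(0), integer(0), integer(0), text))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  toks <- tolower(substring(text, start, start + len - 1L))
  new_token_sequence(toks, start, start + len, text)
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> ", length(x$tokens), " tokens: ",
      paste(utils::head(x$tokens, 12L), collapse = " "),
      if (length(x$tokens) > 12L) " ..." else "", "\n", sep = "")
  invisible(x)
}

# Abbreviations whose trailing period must not end a sentence.
.sentence_abbrev <- c("dr", "mr", "mrs", "ms", "prof", "sr", "jr", "st",
                      "vs", "etc", "e.g", "i.e", "eg", "ie", "cf", "al",
                      "approx", "fig", "no", "dept")

#' Split text into sentences
#'
#' Rule-based segmentation: a run of terminal punctuation (`. ! ?`) ends a
#' sentence when followed by whitespace plus a capital letter or digit, or by
#' end of text. Decimal numbers never split (no whitespace follows the dot)
#' and a small abbreviation list (`"Dr."`, `"e.g."`, ...) is protected.
#'
#' @param text A length-one character string.
#' @return A `sentence_list` with `sentences` and their offsets (`start`
#'   1-based, `end` exclusive) covering all non-whitespace text.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- structure(list(sentences = character(0), start = integer(0),
                          end = integer(0), text = text %||% ""),
                     class = "sentence_list")
  if (is.na(text) || !nzchar(text) || !grepl("[^[:space:]]", text)) {
    return(empty)
  }
  n <- nchar(text)
  breaks <- integer(0)
  m <- gregexpr("[.!?]+", text)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      s <- as.integer(m[i])
      e <- s + attr(m, "match.length")[i] - 1L
      rest <- if (e < n) substring(text, e + 1L, n) else ""
      at_end <- !grepl("[^[:space:]]", rest)
      followed <- grepl("^[[:space:]]+[\"'(]?[[:upper:][:digit:]]", rest)
      if (!(at_end || followed)) next
      before <- substring(text, max(1L, s - 12L), s - 1L)
      w <- regmatches(before, regexpr("[[:alnum:].]+$", before))
      if (length(w) == 1L) {
        w <- tolower(sub("\\.+$", "", w))
        if (w %in% .sentence_abbrev) next
        if (grepl("^[[:alpha:]]$", w) && !at_end) next  # initials ("J. Smith")
      }
      breaks <- c(breaks, e)
    }
  }
  bounds <- unique(c(breaks[breaks < n], n))
  sentences <- character(0); starts <- integer(0); ends <- integer(0)
  pos <- 1L
  for (b in bounds) {
    seg <- substring(text, pos, b)
    lead <- regexpr("[^[:space:]]", seg)
    if (lead > 0L) {
      trail <- as.integer(regexpr("[[:space:]]*$", seg)) - 1L
      s0 <- pos + as.integer(lead) - 1L
      e0 <- pos + trail - 1L
      sentences <- c(sentences, substring(text, s0, e0))
      starts <- c(starts, s0)
      ends <- c(ends, e0 + 1L)
    }
    pos <- b + 1L
  }
  structure(list(sentences = sentences, start = starts, end = ends,
                 text = text),
            class = "sentence_list")
}

#' @export
print.sentence_list <- function(x, ...) {
  cat("<sentence_list> ", length(x$sentences), " sentences\n", sep = "")
  invisible(x)
}

#' Normalized edit-distance similarity between token vectors
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, computed for every
#' pair. Two empty strings have similarity 1.
#'
#' @param a,b Character vectors of tokens.
#' @return A `length(a)` x `length(b)` similarity matrix in `[0, 1]`.
#' @export
token_similarity <- function(a, b) {
  d <- utils::adist(a, b)
  ml <- outer(nchar(a), nchar(b), pmax)
  s <- 1 - d / ml
  s[ml == 0] <- 1
  s
}

as_tokens <- function(x) {
  if (inherits(x, "token_sequence")) return(x$tokens)
  if (is.character(x)) {
    if (length(x) == 1L) return(tokenize(x)$tokens)
    return(x)
  }
  stop("expected a token_sequence, a single string, or a token vector")
}

#' Fuzzy Jaccard similarity between two token sets
#'
#' Unique tokens of `a` and `b` are paired greedily in descending
#' edit-distance similarity (each token used at most once); tokens match when
#' their similarity is at least `match_threshold`. The score is
#' `|matches| / |fuzzy union|`. At `match_threshold = 1` this is exact set
#' Jaccard. Two empty sets score 1 and carry a `degenerate` attribute.
#'
#' @param a,b `token_sequence` objects, single strings (tokenized first), or
#'   character vectors of tokens.
#' @param match_threshold Similarity needed for two tokens to match, in
#'   `[0, 1]`; default 0.85 tolerates plural/inflection variants.
#' @return A number in `[0, 1]`.
#' @examples
#' fuzzy_jaccard("wound care daily", "wound care daily")
#' fuzzy_jaccard(c("dressing", "change", "48"),
#'               c("dressings", "change", "48", "hours"), 0.8)
#' @export
fuzzy_jaccard <- function(a, b, match_threshold = 0.85) {
  stopifnot(match_threshold >= 0, match_threshold <= 1)
  A <- unique(as_tokens(a))
  B <- unique(as_tokens(b))
  if (!length(A) && !length(B)) {
    return(structure(1, degenerate = TRUE))
  }
  if (!length(A) || !length(B)) return(0)
  if (length(A) == length(B) && setequal(A, B)) return(1)
  S <- token_similarity(A, B)
  ok <- which(S >= match_threshold, arr.ind = TRUE)
  m <- 0L
  if (nrow(ok)) {
    ord <- order(-S[ok], ok[, 1], ok[, 2])
    used_a <- logical(length(A))
    used_b <- logical(length(B))
    for (r in ord) {
      i <- ok[r, 1]; j <- ok[r, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE; m <- m + 1L
      }
    }
  }
  m / (length(A) + length(B) - m)
}
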