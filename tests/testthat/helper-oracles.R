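# Independent brute-force oracles. Each reimplements a quantity from first
# principles (enumeration, direct formula evaluation, pair counting) so the
# package implementation is checked against a second, independent route.

# Character-class brute-force tokenizer: scan characters, accumulate runs of
# [alnum] allowing '.'/'-' only between alphanumerics.
oracle_tokenize <- function(text) {
  chars <- strsplit(tolower(text), "")[[1]]
  is_an <- grepl("[[:alnum:]]", chars)
  toks <- character(0); cur <- ""
  i <- 1L
  while (i <= length(chars)) {
    if (is_an[i]) {
      cur <- paste0(cur, chars[i])
    } else if (nzchar(cur) && chars[i] %in% c(".", "-") &&
               i < length(chars) && is_an[i + 1L]) {
      cur <- paste0(cur, chars[i])
    } else if (nzchar(cur)) {
      toks <- c(toks, cur); cur <- ""
    }
    i <- i + 1L
  }
  if (nzchar(cur)) toks <- c(toks, cur)
  toks
}

oracle_sim <- function(a, b) 1 - utils::adist(a, b) / max(nchar(a), nchar(b))

# Exact-assignment fuzzy Jaccard: enumerate all one-to-one pairings of the
# unique token sets and take the maximum number of matched pairs.
oracle_fuzzy_jaccard <- function(a, b, thr) {
  A <- unique(a); B <- unique(b)
  if (!length(A) && !length(B)) return(1)
  if (!length(A) || !length(B)) return(0)
  S <- outer(A, B, Vectorize(oracle_sim))
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (length(A) - i + 1L) <= best) return()
    if (i > length(A)) { best <<- max(best, count); return() }
    for (j in seq_along(B)) {
      if (!used[j] && S[i, j] >= thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, logical(length(B)), 0L)
  best / (length(A) + length(B) - best)
}

# Okapi BM25 by direct formula evaluation over explicit token lists.
oracle_bm25 <- function(query_tokens, doc_tokens_list, k1 = 1.5, b = 0.75) {
  N <- length(doc_tokens_list)
  avgdl <- mean(lengths(doc_tokens_list))
  vapply(doc_tokens_list, function(d) {
    s <- 0
    for (t in unique(query_tokens)) {
      df <- sum(vapply(doc_tokens_list, function(x) t %in% x, logical(1)))
      f <- sum(d == t)
      idf <- log((N - df + 0.5) / (df + 0.5) + 1)
      s <- s + idf * f * (k1 + 1) / (f + k1 * (1 - b + b * length(d) / avgdl))
    }
    s
  }, numeric(1))
}

# Step-by-step MMR: at each step score every remaining candidate directly.
oracle_mmr <- function(query_sims, cand_sims, n_select, lambda) {
  selected <- integer(0)
  remaining <- seq_along(query_sims)
  while (length(selected) < min(n_select, length(query_sims))) {
    scores <- vapply(remaining, function(d) {
      red <- if (length(selected)) max(cand_sims[d, selected]) else 0
      lambda * query_sims[d] - (1 - lambda) * red
    }, numeric(1))
    pick <- remaining[order(-scores, remaining)[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# Fleiss kappa by counting agreeing rater pairs directly.
oracle_fleiss <- function(counts) {
  n <- unique(rowSums(counts))
  agree <- vapply(seq_len(nrow(counts)), function(i) {
    sum(counts[i, ] * (counts[i, ] - 1)) / (n * (n - 1))
  }, numeric(1))
  p_bar <- mean(agree)
  pj <- colSums(counts) / sum(counts)
  (p_bar - sum(pj^2)) / (1 - sum(pj^2))
}

# Krippendorff alpha by enumerating every pairable value pair.
oracle_krippendorff_nominal <- function(mat) {
  pairs_o <- c(); vals_all <- c()
  for (u in seq_len(nrow(mat))) {
    r <- mat[u, ][!is.na(mat[u, ])]
    if (length(r) < 2) next
    m <- length(r)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) pairs_o <- c(pairs_o, (r[i] != r[j]) / (m - 1))
    }
    vals_all <- c(vals_all, rep(r, 1))
  }
  n <- length(vals_all)
  d_o <- sum(pairs_o) / n
  tab <- table(vals_all)
  d_e <- (sum(outer(tab, tab)) - sum(tab^2)) / (n * (n - 1))
  1 - d_o / d_e
}

# ICC mean squares from a two-way ANOVA fitted with stats::aov.
oracle_icc_ms <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   item = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  a <- summary(stats::aov(y ~ item + rater, data = df))[[1]]
  list(msr = a["item", "Mean Sq"], msc = a["rater", "Mean Sq"],
       mse = a["Residuals", "Mean Sq"])
}

# Longest common subsequence by simple recursion with memoisation.
oracle_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) f(i - 1L, j - 1L) + 1L else {
      max(f(i - 1L, j), f(i, j - 1L))
    }
    memo[[key]] <- v
    v
  }
  f(length(a), length(b))
}

# small fixed toy knowledge base used across pipeline tests
toy_docs <- function() {
  list(
    ragcare:::new_source_document(
      "toy-01", "Wound Care", "Wound Care",
      paste("Keep the incision dry for 48 hours after surgery.",
            "Change the dressing once daily with clean hands.",
            "A small amount of clear fluid is normal in the first 3 days.",
            "Call the clinic if redness spreads beyond the incision edge.",
            "Wash your hands for 20 seconds before touching the dressing.")),
    ragcare:::new_source_document(
      "toy-02", "Showering and Bathing", "Showering",
      paste("You may shower 48 hours after surgery.",
            "Pat the incision dry with a clean towel after showering.",
            "No baths, hot tubs, or pools until 3 weeks after surgery.",
            "Use warm, not hot, water for the first week.",
            "Keep the first showers short, about 5 to 10 minutes.")),
    ragcare:::new_source_document(
      "toy-03", "Traveling", "Traveling",
      paste("You may drive again when you can brake hard without pain.",
            "On long car rides, stop every 60 to 90 minutes to walk.",
            "Carry medication in its original labeled containers.",
            "Stay within 1 hour of the clinic for the first week.",
            "Knee-high compression stockings are recommended for travel over 4 hours.")))
}

toy_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$chunking$chunk_limit <- 200L
  cfg
}
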