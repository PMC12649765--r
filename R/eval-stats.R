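# Human-evaluation mathematics: majority-vote consensus, micro-averaged
# confusion-matrix metrics with Wald and Wilson 95% intervals, topic-level
# accuracy summaries, Likert/SSI aggregation, and the inter-rater
# reliability suite (Fleiss' and Cohen's kappa, Krippendorff's alpha,
# two-way random-effects ICC). Coefficients that are undefined (zero
# expected disagreement) are flagged explicitly, never silently zeroed.

#' Majority-vote consensus labels
#'
#' @param labels Items x raters matrix (or data.frame) of binary labels.
#' @return Integer vector of per-item consensus labels (majority vote; with
#'   3 raters no ties are possible; an even split errors).
#' @export
consensus_labels <- function(labels) {
  m <- as.matrix(labels)
  stopifnot(ncol(m) >= 2, all(m %in% c(0, 1)))
  s <- rowSums(m)
  if (any(2 * s == ncol(m))) stop("tied vote: even rater count with a split")
  as.integer(s > ncol(m) / 2)
}

#' Confusion matrix container
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

wald_ci <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(lower = max(0, p - z * se), upper = min(1, p + z * se))
}

wilson_ci <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Micro-averaged classification metrics with confidence intervals
#'
#' Accuracy `(tp+tn)/N`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and F1,
#' plus Wald and Wilson 95% intervals for accuracy and recall. A precision
#' with `tp + fp = 0` is reported as `NA` with `precision_undefined = TRUE`
#' rather than a number.
#'
#' @param cm A [confusion_matrix()].
#' @param level Confidence level (default 0.95).
#' @return A list of metrics and intervals.
#' @export
classification_metrics <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stop("empty confusion matrix")
  acc <- (cm$tp + cm$tn) / n
  prec_und <- (cm$tp + cm$fp) == 0
  prec <- if (prec_und) NA_real_ else cm$tp / (cm$tp + cm$fp)
  rec <- if (cm$tp + cm$fn == 0) NA_real_ else cm$tp / (cm$tp + cm$fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       precision_undefined = prec_und,
       accuracy_ci_wald = wald_ci(acc, n, level),
       accuracy_ci_wilson = wilson_ci(acc, n, level),
       recall_ci_wald = if (!is.na(rec)) wald_ci(rec, cm$tp + cm$fn, level),
       recall_ci_wilson = if (!is.na(rec)) wilson_ci(rec, cm$tp + cm$fn, level),
       n = n)
}

#' Topic-level accuracy summary
#'
#' Unweighted mean over topics, sample SD (n - 1 denominator), and range.
#'
#' @param per_topic data.frame with columns `topic`, `n_correct`, `n_total`.
#' @return List: `per_topic` (with an `accuracy` column), `mean`, `sd`,
#'   `range`.
#' @export
topic_accuracy <- function(per_topic) {
  stopifnot(all(c("topic", "n_correct", "n_total") %in% names(per_topic)),
            all(per_topic$n_total > 0))
  acc <- per_topic$n_correct / per_topic$n_total
  list(per_topic = cbind(per_topic, accuracy = acc),
       mean = mean(acc),
       sd = stats::sd(acc),
       range = range(acc))
}

#' Summarize a Likert or SSI rating field
#'
#' @param ratings data.frame of rating records with columns `query_id`,
#'   `reviewer_id` and the rating fields.
#' @param field One of `"completeness"`, `"consistency"`, `"ssi"`.
#' @return List: overall `mean`, `per_reviewer` means, `distribution`.
#' @export
likert_summary <- function(ratings, field = c("completeness", "consistency",
                                              "ssi")) {
  field <- match.arg(field)
  x <- ratings[[field]]
  stopifnot(!is.null(x))
  list(mean = mean(x),
       per_reviewer = tapply(x, ratings$reviewer_id, mean),
       distribution = table(x))
}

#' Fleiss' kappa for multiple raters
#'
#' `P_i = (sum_j n_ij^2 - n) / (n(n-1))`, `kappa = (P_bar - P_e)/(1 - P_e)`
#' with `P_e = sum_j p_j^2`. When `P_e = 1` (a single shared category) the
#' coefficient is undefined and flagged.
#'
#' @param table Items x categories count matrix; every row sums to the
#'   common rater count `n`.
#' @return List: `kappa`, `p_bar`, `p_e`, `undefined`.
#' @export
fleiss_kappa <- function(table) {
  m <- as.matrix(table)
  n <- unique(rowSums(m))
  stopifnot(length(n) == 1, n >= 2)
  p_i <- (rowSums(m^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / sum(m)
  p_e <- sum(p_j^2)
  if (abs(1 - p_e) < 1e-12) {
    return(list(kappa = NA_real_, p_bar = p_bar, p_e = p_e, undefined = TRUE))
  }
  list(kappa = (p_bar - p_e) / (1 - p_e), p_bar = p_bar, p_e = p_e,
       undefined = FALSE)
}

#' Cohen's kappa for two raters
#'
#' @param x,y Label vectors of equal length.
#' @return List: `kappa`, `p_o`, `p_e`, `undefined`.
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  lev <- sort(unique(c(x, y)))
  tab <- table(factor(x, lev), factor(y, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    return(list(kappa = NA_real_, p_o = p_o, p_e = p_e, undefined = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e,
       undefined = FALSE)
}

#' Pairwise Cohen's kappa across reviewers
#'
#' @param labels Items x raters matrix of labels.
#' @return List: `pairs` (data.frame of per-pair kappas), `mean`, `range`.
#' @export
pairwise_cohen_kappa <- function(labels) {
  m <- as.matrix(labels)
  stopifnot(ncol(m) >= 2)
  cols <- colnames(m) %||% paste0("R", seq_len(ncol(m)))
  out <- list()
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in seq(i + 1L, ncol(m))) {
      k <- cohen_kappa(m[, i], m[, j])
      out[[length(out) + 1L]] <- data.frame(
        rater_a = cols[i], rater_b = cols[j], kappa = k$kappa,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  list(pairs = pairs, mean = mean(pairs$kappa),
       range = range(pairs$kappa))
}

#' Krippendorff's alpha (nominal or ordinal)
#'
#' Coincidence-matrix construction with missing entries allowed;
#' `alpha = 1 - D_o / D_e` with nominal 0/1 distance or ordinal
#' cumulative-margin squared distance. Degenerate data (`D_e = 0`) is
#' flagged undefined.
#'
#' @param data Items x raters matrix of ratings; `NA` for missing.
#' @param level `"nominal"` or `"ordinal"`.
#' @return List: `alpha`, `d_o`, `d_e`, `undefined`.
#' @export
krippendorff_alpha <- function(data, level = c("nominal", "ordinal")) {
  level <- match.arg(level)
  m <- as.matrix(data)
  vals <- sort(unique(stats::na.omit(as.vector(m))))
  k <- length(vals)
  O <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in seq_len(nrow(m))) {
    r <- stats::na.omit(as.vector(m[u, ]))
    mu <- length(r)
    if (mu < 2) next
    idx <- match(r, vals)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) O[idx[i], idx[j]] <- O[idx[i], idx[j]] + 1 / (mu - 1)
      }
    }
  }
  nc <- rowSums(O)
  n <- sum(nc)
  if (n < 2) return(list(alpha = NA_real_, d_o = NA_real_, d_e = NA_real_,
                         undefined = TRUE))
  delta <- matrix(0, k, k)
  if (level == "nominal") {
    delta <- 1 - diag(k)
  } else {
    for (c1 in seq_len(k)) {
      for (c2 in seq_len(k)) {
        if (c1 == c2) next
        lo <- min(c1, c2); hi <- max(c1, c2)
        delta[c1, c2] <- (sum(nc[lo:hi]) - (nc[c1] + nc[c2]) / 2)^2
      }
    }
  }
  d_o <- sum(O * delta) / n
  d_e <- sum(outer(nc, nc) * delta) / (n * (n - 1))
  if (d_e <= .Machine$double.eps) {
    return(list(alpha = NA_real_, d_o = d_o, d_e = d_e, undefined = TRUE))
  }
  list(alpha = 1 - d_o / d_e, d_o = d_o, d_e = d_e, undefined = FALSE)
}

#' Two-way random-effects intraclass correlation
#'
#' ANOVA decomposition of a complete items x raters matrix:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` and
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#'
#' @param ratings Complete numeric items x raters matrix (>= 2 each).
#' @param form `"single"` for ICC(2,1), `"average"` for ICC(2,k).
#' @return List: `icc`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`.
#' @export
icc_two_way <- function(ratings, form = c("single", "average")) {
  form <- match.arg(form)
  m <- as.matrix(ratings)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2, !anyNA(m))
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  sst <- sum((m - g)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  icc <- if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse, n = n, k = k)
}
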