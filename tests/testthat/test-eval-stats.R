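test_that("majority-vote consensus matches the count rule", {
  expect_equal(consensus_labels(matrix(c(1, 1, 0), 1)), 1L)
  expect_equal(consensus_labels(matrix(c(0, 0, 0), 1)), 0L)
  set.seed(31)
  m <- matrix(rbinom(750, 1, 0.7), ncol = 3)
  expect_equal(consensus_labels(m), as.integer(rowSums(m) > 1.5))
  expect_error(consensus_labels(matrix(c(1, 0), 1)), "tie")
})

test_that("classification metrics handle perfection and degeneracy", {
  perf <- classification_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$precision, 1)
  expect_equal(perf$recall, 1)
  expect_equal(perf$f1, 1)
  deg <- classification_metrics(confusion_matrix(0, 0, 5, 5))
  expect_equal(deg$recall, 0)
  expect_true(deg$precision_undefined)
  expect_true(is.na(deg$precision))
  expect_error(classification_metrics(confusion_matrix(0, 0, 0, 0)))
})

test_that("Wald and Wilson intervals bracket the point estimate", {
  m <- classification_metrics(confusion_matrix(196, 0, 4, 50))
  for (ci in list(m$accuracy_ci_wald, m$accuracy_ci_wilson)) {
    expect_lt(ci[["lower"]], m$accuracy)
    expect_gt(ci[["upper"]], m$accuracy)
  }
  # Wilson never escapes [0, 1] even at extreme proportions
  e <- classification_metrics(confusion_matrix(10, 0, 0, 0))
  expect_lte(e$accuracy_ci_wilson[["upper"]], 1)
})

test_that("topic accuracy summary matches direct formula evaluation", {
  tab <- data.frame(topic = letters[1:5],
                    n_correct = c(9, 10, 8, 10, 7),
                    n_total = c(10, 10, 10, 10, 10))
  s <- topic_accuracy(tab)
  acc <- tab$n_correct / tab$n_total
  expect_equal(s$mean, mean(acc))
  expect_equal(s$sd, sqrt(sum((acc - mean(acc))^2) / 4))
  expect_equal(s$range, c(0.7, 1))
  flat <- topic_accuracy(data.frame(topic = c("a", "b"),
                                    n_correct = c(5, 5), n_total = c(5, 5)))
  expect_equal(flat$sd, 0)
})

test_that("likert summaries are plain arithmetic means", {
  r <- data.frame(query_id = rep("q1", 3), reviewer_id = c("R1", "R2", "R3"),
                  completeness = c(5, 5, 4), consistency = c(5, 5, 5),
                  ssi = c(3, 2, 3))
  expect_equal(likert_summary(r, "completeness")$mean, 14 / 3)
  expect_equal(likert_summary(r, "consistency")$mean, 5)
  expect_equal(unname(likert_summary(r, "ssi")$per_reviewer["R2"]), 2)
})

test_that("Fleiss kappa follows the formula and the pair-counting oracle", {
  # single item rated (2,1) across 3 raters has P_i = 1/3
  m <- matrix(c(2, 1), 1)
  n <- 3
  expect_equal((sum(m^2) - n) / (n * (n - 1)), 1 / 3)
  # perfect agreement with mixed categories
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  # published-style 4-rater table vs brute-force pair counting
  set.seed(12)
  tab <- t(vapply(1:30, function(i) {
    tabulate(sample(1:3, 4, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
             nbins = 3)
  }, integer(3)))
  expect_equal(fleiss_kappa(tab)$kappa, oracle_fleiss(tab), tolerance = 1e-12)
  # degenerate: one shared category only
  expect_true(fleiss_kappa(matrix(c(3, 0, 3, 0), 2, byrow = TRUE))$undefined)
})

test_that("Cohen kappa matches hand computation and the null simulation", {
  # 2x2 toy table: raters agree on 45+35 of 100; marginals 50/50 and 60/40
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 45), rep(0, 5), rep(1, 15), rep(0, 35))
  k <- cohen_kappa(x, y)
  p_o <- 0.80
  p_e <- 0.5 * 0.6 + 0.5 * 0.4
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0))$kappa, 1)
  set.seed(77)
  a <- rbinom(10000, 1, 0.5); b <- rbinom(10000, 1, 0.5)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
})

test_that("pairwise Cohen kappa aggregates all rater pairs", {
  set.seed(8)
  m <- cbind(R1 = rbinom(200, 1, 0.6), R2 = rbinom(200, 1, 0.6),
             R3 = rbinom(200, 1, 0.6))
  pw <- pairwise_cohen_kappa(m)
  expect_equal(nrow(pw$pairs), 3L)
  expect_equal(pw$mean, mean(pw$pairs$kappa))
  expect_equal(pw$range, range(pw$pairs$kappa))
})

test_that("Krippendorff alpha handles missing data like the pairable oracle", {
  m <- rbind(c(1, 1, NA), c(0, 0, 0), c(1, 0, 1), c(NA, 1, 1), c(0, 0, NA))
  got <- krippendorff_alpha(m, "nominal")
  expect_equal(got$alpha, oracle_krippendorff_nominal(m), tolerance = 1e-12)
  perfect <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, 1, 1))
  expect_equal(krippendorff_alpha(perfect, "nominal")$alpha, 1)
  expect_equal(krippendorff_alpha(perfect, "ordinal")$alpha, 1)
  expect_true(krippendorff_alpha(rbind(c(1, 1), c(1, 1)), "nominal")$undefined)
})

test_that("ordinal alpha penalizes distant categories more than adjacent", {
  adjacent <- rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 2), c(4, 3), c(2, 1))
  distant <- rbind(c(1, 4), c(2, 3), c(3, 2), c(1, 4), c(4, 1), c(2, 1))
  a1 <- krippendorff_alpha(adjacent, "ordinal")$alpha
  a2 <- krippendorff_alpha(distant, "ordinal")$alpha
  expect_gt(a1, a2)
})

test_that("Krippendorff nominal alpha converges to Fleiss kappa on large data", {
  set.seed(100)
  n <- 3000
  truth <- rbinom(n, 1, 0.5)
  lab <- vapply(1:3, function(r) {
    ifelse(runif(n) < 0.85, truth, rbinom(n, 1, 0.5))
  }, numeric(n))
  counts <- t(vapply(seq_len(n), function(i) {
    tabulate(lab[i, ] + 1, nbins = 2)
  }, integer(2)))
  fk <- fleiss_kappa(counts)$kappa
  ka <- krippendorff_alpha(lab, "nominal")$alpha
  expect_lt(abs(fk - ka), 0.02)
})

test_that("two-rater Fleiss kappa equals Cohen kappa under matched marginals", {
  # with identical marginal distributions Scott's pi (= 2-rater Fleiss)
  # coincides with Cohen's kappa
  x <- c(rep(1, 60), rep(0, 40))
  y <- c(rep(1, 45), rep(0, 15), rep(1, 15), rep(0, 25))
  stopifnot(mean(x) == mean(y))
  counts <- t(vapply(seq_along(x), function(i) {
    tabulate(c(x[i], y[i]) + 1, nbins = 2)
  }, integer(2)))
  expect_equal(fleiss_kappa(counts)$kappa, cohen_kappa(x, y)$kappa,
               tolerance = 1e-12)
})

test_that("ICC forms match a from-scratch ANOVA on a 6x3 matrix", {
  m <- matrix(c(9, 2, 5, 8, 2, 1, 3, 6,
                2, 4, 4, 6, 6, 7, 8, 6, 10, 6), nrow = 6)
  ms <- oracle_icc_ms(m)
  single <- icc_two_way(m, "single")
  average <- icc_two_way(m, "average")
  expect_equal(single$ms_rows, ms$msr, tolerance = 1e-10)
  expect_equal(single$ms_cols, ms$msc, tolerance = 1e-10)
  expect_equal(single$ms_error, ms$mse, tolerance = 1e-10)
  n <- 6; k <- 3
  expect_equal(single$icc,
               (ms$msr - ms$mse) /
                 (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n),
               tolerance = 1e-10)
  expect_equal(average$icc,
               (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n),
               tolerance = 1e-10)
})

test_that("ICC(2,k) is 1 when rater columns duplicate item effects", {
  m <- matrix(rep(c(4, 7, 1, 9, 5), 3), ncol = 3)
  expect_equal(icc_two_way(m, "average")$icc, 1)
  expect_equal(icc_two_way(m, "single")$icc, 1)
})

test_that("ICC(2,1) recovers known variance components in simulation", {
  set.seed(55)
  n <- 500; k <- 3
  item <- rnorm(n, sd = 2)
  rater <- rnorm(k, sd = 1)
  m <- outer(item, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k), n, k)
  got <- icc_two_way(m, "single")$icc
  expect_lt(abs(got - 4 / 6), 0.06)
})

test_that("all reliability coefficients stay at or below 1", {
  set.seed(14)
  for (rep in 1:10) {
    lab <- matrix(rbinom(60, 1, runif(1, 0.2, 0.8)), ncol = 3)
    counts <- t(apply(lab, 1, function(r) tabulate(r + 1, nbins = 2)))
    fk <- fleiss_kappa(counts)
    if (!fk$undefined) expect_lte(fk$kappa, 1)
    ka <- krippendorff_alpha(lab, "nominal")
    if (!ka$undefined) expect_lte(ka$alpha, 1)
  }
})
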