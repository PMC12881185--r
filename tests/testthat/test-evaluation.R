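test_that("AUC handles perfect separation, ties, and the sign identity", {
  labels <- c(rep("R", 4), rep("NR", 6))
  expect_equal(rocAuc(c(5, 6, 7, 8, 1, 2, 3, 4, 0, 1), labels)$auc, 1)
  expect_equal(rocAuc(rep(1, 10), labels)$auc, 0.5)
  set.seed(10)
  s <- sample(1:5, 10, replace = TRUE)
  expect_equal(rocAuc(s, labels)$auc + rocAuc(-s, labels)$auc, 1)
  expect_error(rocAuc(1:4, rep("R", 4)), "both classes")
})

test_that("rank-based AUC equals exhaustive pairwise comparison", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c("R", "NR"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAuc(s, labels)$auc, pairwiseAuc(s, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals trapezoidal integration of its own ROC curve", {
  set.seed(12)
  s <- round(rnorm(40), 1)
  labels <- sample(c("R", "NR"), 40, replace = TRUE)
  roc <- rocAuc(s, labels)
  fpr <- 1 - roc$specificity
  ord <- order(fpr, roc$sensitivity)
  x <- fpr[ord]; y <- roc$sensitivity[ord]
  trap <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  expect_equal(roc$auc, trap, tolerance = 1e-12)
})

test_that("confusion metrics reproduce the imbalanced-cohort F1 values", {
  # precision 0.375 with perfect recall: 3 true responders, 5 false calls
  calls1 <- c(rep("R", 8), rep("NR", 10))
  labels1 <- c(rep("R", 3), rep("NR", 15))
  m1 <- confusionMetrics(calls1, labels1)
  expect_equal(m1$precision, 0.375)
  expect_equal(m1$recall, 1.0)
  expect_equal(round(m1$f1, 3), 0.545)

  # precision 0.385 with perfect recall: 5 true responders among 13 calls
  calls2 <- c(rep("R", 13), rep("NR", 18))
  labels2 <- c(rep("R", 5), rep("NR", 26))
  m2 <- confusionMetrics(calls2, labels2)
  expect_equal(round(m2$precision, 3), 0.385)
  expect_equal(m2$recall, 1.0)
  expect_equal(round(m2$f1, 3), 0.556)

  perfect <- confusionMetrics(labels1, labels1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  noCalls <- confusionMetrics(rep("NR", 4), c("R", "R", "NR", "NR"))
  expect_true(is.na(noCalls$precision))
  expect_true(is.na(noCalls$f1))
})

test_that("response rates report per-group fractions and counts", {
  groups <- c("high", "high", "high", "high", "low", "low")
  labels <- c("R", "R", "R", "NR", "NR", "NR")
  rr <- responseRates(groups, labels)
  expect_equal(rr$rate[rr$group == "high"], 0.75)
  expect_equal(rr$rate[rr$group == "low"], 0)
  expect_equal(attr(rr, "difference"), 0.75)

  # Gide-like composition: 11 responders of 18 is ~61%
  labs <- c(rep("R", 11), rep("NR", 7))
  rrAll <- suppressWarnings(responseRates(rep("high", 18), labs))
  expect_equal(round(100 * rrAll$rate[rrAll$group == "high"]), 61)
  expect_warning(responseRates(rep("high", 18), labs), "empty group")

  perm <- sample(6)
  expect_equal(suppressWarnings(responseRates(groups[perm], labels[perm])),
               suppressWarnings(responseRates(groups, labels)),
               ignore_attr = TRUE)
})

test_that("one-tailed rank test: exact enumeration and approximation", {
  # all three R values above all three NR values: p = 1/C(6,3) = 0.05
  res <- wilcoxonOneTailed(c(4, 5, 6), c(1, 2, 3))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.05)

  same <- wilcoxonOneTailed(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p.value, 0.3)
  expect_lt(same$p.value, 0.7)

  # exact and normal-approximation branches agree on tie-free n = 12
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    pExact <- wilcoxonOneTailed(x, y)$p.value
    pApprox <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                         correct = TRUE)$p.value)
    expect_lt(abs(pExact - pApprox), 0.02)
  }
})

test_that("chi-square association follows the Pearson statistic", {
  # proportional rows: perfect independence
  g <- rep(c("high", "low"), each = 20)
  v <- rep(c("A", "B"), times = 20)
  res <- chiSquareAssociation(g, v)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  # diagonal 2x2 table (10,0;0,10): chi-square 20 on 1 df
  g2 <- rep(c("high", "low"), each = 10)
  v2 <- rep(c("A", "B"), each = 10)
  res2 <- chiSquareAssociation(g2, v2)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  swapped <- chiSquareAssociation(ifelse(g2 == "high", "low", "high"), v2)
  expect_equal(swapped$statistic, res2$statistic)
})

test_that("chi-square rejects degenerate margins", {
  expect_error(
    chiSquareAssociation(c("high", "high"), c("A", "B")),
    "zero margin")
})

test_that("p-value wording follows the significance/trend convention", {
  expect_identical(pValueLabel(c(0.01, 0.07, 0.2)),
                   c("significant", "trend", "ns"))
})
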