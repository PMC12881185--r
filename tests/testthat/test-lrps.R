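.toySignature <- function(w, theta = 0.5, intercept = 0, offset = 0,
                          orCutoff = 1) {
  pairs <- names(w)
  new("LRSignature",
      selectedPairs = pairs, effectSizes = w,
      geneSets = setNames(lapply(pairs, function(p) c(p, "X")), pairs),
      intercept = intercept, offset = offset, lambdaOpt = 0.1,
      alpha = 0.5, tau = 2 / 3, exponent = 0.25, normalization = "raw",
      youdenThreshold = theta, orCutoff = orCutoff, provenance = list())
}

test_that("LRPS is the |w|-normalized weighted average of pair scores", {
  sig1 <- .toySignature(c(PA = 1))
  expect_equal(unname(lrps(sig1, c(PA = 0.42))), 0.42)

  sig2 <- .toySignature(c(PA = 2, PB = -1))
  expect_equal(unname(lrps(sig2, c(PA = 0.6, PB = 0.3))), 0.3)
  # positive rescaling of the weights leaves the score unchanged
  sig2s <- .toySignature(c(PA = 2, PB = -1) * 7.3)
  expect_equal(lrps(sig2s, c(PA = 0.6, PB = 0.3)),
               lrps(sig2, c(PA = 0.6, PB = 0.3)))
})

test_that("missing selected pairs and empty signatures are errors", {
  sig2 <- .toySignature(c(PA = 2, PB = -1))
  expect_error(lrps(sig2, c(PA = 0.6)), "lacks selected pair")
  sigEmpty <- new("LRSignature",
                  selectedPairs = character(0),
                  effectSizes = setNames(numeric(0), character(0)),
                  geneSets = setNames(list(), character(0)),
                  intercept = 0, offset = 0, lambdaOpt = 1, alpha = 0.5,
                  tau = 2 / 3, exponent = 0.25, normalization = "raw",
                  youdenThreshold = 0.5, orCutoff = 1, provenance = list())
  expect_error(lrps(sigEmpty, c(PA = 1)), "empty signature")
})

test_that("per-sample probability and odds follow the logistic identities", {
  sig <- .toySignature(c(PA = 1), intercept = 0)
  at0 <- sampleOdds(sig, c(PA = 0))
  expect_equal(at0$prob, 0.5)
  expect_equal(at0$odds_ratio, 1.0)
  atLog3 <- sampleOdds(sig, c(PA = log(3)))
  expect_equal(atLog3$prob, 0.75)
  expect_equal(atLog3$odds_ratio, 3.0)
  # offset convention: dropped by default, retained on request
  sigOff <- .toySignature(c(PA = 1), offset = -0.7)
  expect_equal(sampleOdds(sigOff, c(PA = 0))$prob, 0.5)
  expect_equal(sampleOdds(sigOff, c(PA = 0), includeOffset = TRUE)$prob,
               plogis(-0.7))
  # centered odds ratio
  m <- matrix(c(0, 1, 2), nrow = 1, dimnames = list("PA", c("a", "b", "c")))
  cent <- sampleOdds(sig, m, orType = "centered")$odds_ratio
  expect_equal(cent, exp(c(0, 1, 2) - 1))
})

test_that("odds ratio increases with LRPS when weights share signs", {
  sig <- .toySignature(c(PA = 2, PB = 1))
  s <- matrix(runif(20), nrow = 2, dimnames = list(c("PA", "PB"), NULL))
  colnames(s) <- sprintf("s%d", 1:10)
  l <- lrps(sig, s)
  o <- sampleOdds(sig, s)$odds_ratio
  expect_equal(order(l), order(o))
})

test_that("Youden threshold separates perfectly separable probabilities", {
  probs <- c(rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep("R", 5), rep("NR", 5))
  th <- youdenThreshold(probs, labels)
  expect_gt(th, 0.1)
  expect_lte(th, 0.9)
  calls <- ifelse(probs >= th, "R", "NR")
  expect_identical(calls, labels)
  expect_error(youdenThreshold(probs, rep("R", 10)), "both classes")
})

test_that("Youden threshold matches the brute-force oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    probs <- round(runif(n), 2)
    labels <- sample(c("R", "NR"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(youdenThreshold(probs, labels),
                 bruteYouden(probs, labels))
  }
})

test_that("Youden index is near zero under label permutation", {
  set.seed(3)
  probs <- runif(400)
  labels <- sample(rep(c("R", "NR"), each = 200))
  th <- youdenThreshold(probs, labels)
  calls <- probs >= th
  pos <- labels == "R"
  j <- sum(calls & pos) / sum(pos) + sum(!calls & !pos) / sum(!pos) - 1
  expect_lt(j, 0.2)
})

test_that("high/low grouping uses the mean-OR cutoff with >= ties high", {
  expect_identical(assignGroups(c(1, 3)), c("low", "high"))
  expect_identical(assignGroups(c(2, 2, 2)), rep("high", 3))
  ors <- c(0.5, 1.1, 2.4, 7)
  expect_identical(assignGroups(2 * ors), assignGroups(ors))
})

test_that("assessments are deterministic pure functions of their inputs", {
  co <- quickCohort(seed = 14, n = 40, nPairs = 10, nGenes = 120)
  sm <- scorePairs(cohortExpression(co), makeDefaultCatalog(10))
  clin <- cohortClinical(co)
  fit <- fitEnlr(sm, clin$response, seed = 14)
  sig <- buildSignature(fit, sm, clin$response, makeDefaultCatalog(10))
  a1 <- assessSamples(sig, sm)
  a2 <- assessSamples(sig, sm)
  expect_identical(a1, a2)
  expect_identical(a1$response_call,
                   ifelse(a1$prob >= sig@youdenThreshold, "R", "NR"))
  expect_identical(a1$group,
                   ifelse(a1$odds_ratio >= mean(a1$odds_ratio),
                          "high", "low"))
})

test_that("responders score higher on LRPS in planted-signal cohorts", {
  hits <- 0
  for (seed in 1:10) {
    co <- quickCohort(seed = 400 + seed, n = 80, delta = 2,
                      nPairs = 10, nGenes = 150)
    sm <- scorePairs(cohortExpression(co), makeDefaultCatalog(10))
    clin <- cohortClinical(co)
    fit <- fitEnlr(sm, clin$response, seed = seed)
    if (length(selectedPairs(fit)) == 0) next
    sig <- buildSignature(fit, sm, clin$response, makeDefaultCatalog(10))
    a <- assessSamples(sig, sm)
    p <- wilcoxonOneTailed(a$lrps[clin$response == "R"],
                           a$lrps[clin$response == "NR"])$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
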