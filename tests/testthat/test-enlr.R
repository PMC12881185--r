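test_that("prior-probability offset matches closed forms", {
  expect_equal(computeOffset(10, 10, tau = 1 / 2), 0)
  expect_equal(computeOffset(10, 10, tau = 2 / 3), -log(2))
  # Riaz-like class counts: 21 responders, 33 non-responders
  expect_equal(computeOffset(21, 33, tau = 2 / 3), log(21 / 33) - log(2))
  expect_equal(round(computeOffset(21, 33, tau = 2 / 3), 4), -1.1451)
  expect_error(computeOffset(0, 10), "single class")
  expect_error(computeOffset(5, 5, tau = 1), "tau")
})

test_that("stratified folds balance classes and are deterministic", {
  labels <- rep(c("R", "NR"), each = 10)
  f <- stratifiedFolds(labels, 5, seed = 3)
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == "R"), 2L)
    expect_equal(sum(f == k & labels == "NR"), 2L)
  }
  expect_identical(f, stratifiedFolds(labels, 5, seed = 3))
  expect_false(identical(f, stratifiedFolds(labels, 5, seed = 4)))

  # Lee-like imbalance: 6 R / 29 NR over 5 folds -> 1-2 responders per fold
  lee <- c(rep("R", 6), rep("NR", 29))
  f2 <- stratifiedFolds(lee, 5, seed = 1)
  perFold <- vapply(1:5, function(k) sum(f2 == k & lee == "R"), integer(1))
  expect_true(all(perFold %in% 1:2))
  expect_error(stratifiedFolds(c("R", "NR"), 5), "more folds than samples")
})

.toyScores <- function(seed = 1, n = 40, p = 5, sep = 2) {
  set.seed(seed)
  labels <- rep(c("R", "NR"), length.out = n)
  x <- matrix(rnorm(n * p), nrow = p,
              dimnames = list(paste0("P", 1:p),
                              sprintf("s%02d", 1:n)))
  x[1, labels == "R"] <- x[1, labels == "R"] + sep
  list(x = x, labels = labels)
}

test_that("the largest lambda on the grid zeroes every coefficient", {
  toy <- .toyScores()
  fit <- fitEnlr(toy$x, toy$labels, seed = 1)
  atMax <- coefAtLambda(fit, fit@cvCurve$lambda[1])
  expect_true(all(atMax[-1] == 0))
  expect_true(is.finite(atMax[1]))
})

test_that("a separating feature is selected with a positive coefficient", {
  toy <- .toyScores(sep = 4)
  fit <- fitEnlr(toy$x, toy$labels, seed = 2)
  expect_true("P1" %in% selectedPairs(fit))
  expect_gt(fit@coefficients[["P1"]], 0)
})

test_that("lasso fit agrees with the coordinate-descent oracle", {
  toy <- .toyScores(seed = 8)
  fit <- fitEnlr(toy$x, toy$labels, alpha = 1, seed = 1)
  lam <- fit@cvCurve$lambda[25]
  ours <- coefAtLambda(fit, lam)
  # oracle solves the same objective without standardization; refit the
  # package path unstandardized for a like-for-like comparison
  fitU <- fitEnlr(toy$x, toy$labels, alpha = 1, standardize = FALSE,
                  seed = 1)
  lamU <- fitU@cvCurve$lambda[25]
  oursU <- coefAtLambda(fitU, lamU)
  y01 <- as.integer(toy$labels == "R")
  o <- computeOffset(sum(y01), sum(1 - y01))
  orc <- cdLassoLogistic(t(toy$x), y01, lambda = lamU, offset = o)
  expect_equal(unname(oursU[-1]), orc$beta, tolerance = 1e-4)
  expect_equal(unname(oursU[1]), orc$intercept, tolerance = 1e-4)
})

test_that("support size is non-increasing along the lambda path", {
  toy <- .toyScores(seed = 12, p = 8)
  fit <- fitEnlr(toy$x, toy$labels, seed = 1)
  nsel <- fit@path$df            # features selected per grid lambda
  violations <- sum(diff(rev(nsel)) > 0)
  expect_lte(violations, 1L)
})

test_that("the offset shifts probabilities toward the minority class", {
  set.seed(5)
  n <- 60
  labels <- c(rep("R", 18), rep("NR", 42))   # minority responders
  x <- matrix(rnorm(3 * n), nrow = 3,
              dimnames = list(paste0("P", 1:3), sprintf("s%02d", 1:n)))
  x[1, labels == "R"] <- x[1, labels == "R"] + 1.5
  withOffset <- fitEnlr(x, labels, tau = 2 / 3, seed = 1)
  pihat <- mean(labels == "R")
  neutral <- fitEnlr(x, labels, tau = pihat, seed = 1)  # offset exactly 0
  expect_equal(neutral@offset, 0, tolerance = 1e-12)
  pWith <- sampleOdds(withOffset, x)$prob
  pNeutral <- sampleOdds(neutral, x)$prob
  expect_true(all(pWith >= pNeutral - 1e-8))
  expect_gt(mean(pWith - pNeutral), 0.01)
})

test_that("degenerate inputs are rejected or dropped with a warning", {
  toy <- .toyScores()
  labs1 <- rep("R", 40)
  expect_error(fitEnlr(toy$x, labs1), "at least 2 samples per class")
  xConst <- toy$x
  xConst[2, ] <- 1
  expect_warning(fit <- fitEnlr(xConst, toy$labels, seed = 1),
                 "zero-variance")
  expect_equal(fit@coefficients[["P2"]], 0)
})
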