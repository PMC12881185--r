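test_that("KM estimator matches hand product-limit computations", {
  allCensored <- kmEstimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(allCensored$surv == 1))

  steps <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(steps$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(steps$median, 2)

  # no censoring: KM equals the empirical survival function
  set.seed(2)
  tm <- rexp(50)
  km <- kmEstimate(tm, rep(1, 50))
  emp <- vapply(km$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km$surv, emp)

  # time rescaling moves the axis, not the curve
  km2 <- kmEstimate(3 * c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv, steps$surv)
  expect_equal(km2$time, 3 * steps$time)
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches the manual O-E/V tally and is symmetric", {
  tm <- c(1, 3, 5, 2, 4, 6)
  ev <- rep(1, 6)
  gr <- rep(c("high", "low"), each = 3)
  res <- logrankTest(tm, ev, gr)
  expect_equal(res$statistic, manualLogrank(tm, ev, gr), tolerance = 1e-10)

  swapped <- logrankTest(tm, ev, ifelse(gr == "high", "low", "high"))
  expect_equal(swapped$statistic, res$statistic)

  # identical survival in both groups: statistic 0, p 1
  same <- logrankTest(c(1, 2, 3, 1, 2, 3), rep(1, 6), gr)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  expect_warning(none <- logrankTest(tm, rep(0, 6), gr), "no events")
  expect_equal(none$p.value, 1)
})

test_that("log-rank equals the Cox score test on tie-free data", {
  set.seed(8)
  tm <- rexp(60, rate = c(rep(1, 30), rep(2, 30)))
  gr <- rep(c("a", "b"), each = 30)
  lr <- logrankTest(tm, rep(1, 60), gr)
  cx <- survival::coxph(survival::Surv(tm, rep(1, 60)) ~ gr)
  expect_equal(lr$statistic, unname(summary(cx)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("Cox fit recovers a known two-group hazard ratio", {
  set.seed(13)
  n <- 500
  grp <- rep(c(0, 1), each = n / 2)
  tm <- rexp(n, rate = exp(log(2) * grp))      # true HR = 2
  fit <- coxFit(tm, rep(1, n), data.frame(group = grp))
  hr <- fit$table$hr[fit$table$term == "group"]
  expect_lt(abs(hr - 2) / 2, 0.15)
  expect_true(fit$table$lower[1] < hr & hr < fit$table$upper[1])
})

test_that("constant covariates are reported as HR 1 with a warning", {
  set.seed(4)
  tm <- rexp(30); x <- rnorm(30)
  expect_warning(
    fit <- coxFit(tm, rep(1, 30), data.frame(lrps = x, fixed = 1)),
    "constant across samples")
  row <- fit$table[fit$table$term == "fixed", ]
  expect_equal(row$hr, 1)
  expect_equal(row$coef, 0)
  expect_true(is.infinite(row$se))
})

test_that("hazard coefficient recovery on simulated cohorts is unbiased", {
  gammaHat <- vapply(1:50, function(seed) {
    co <- quickCohort(seed = 6000 + seed, n = 500, delta = 1, nPairs = 8,
                      nGenes = 60, censorRate = 0, hazardCoef = 1)
    clin <- cohortClinical(co)
    z <- cohortTruth(co)$z
    fit <- coxFit(clin$pfs_time, clin$pfs_event, data.frame(z = z))
    -fit$table$coef[1]          # hazard decreases in z
  }, numeric(1))
  expect_lt(abs(mean(gammaHat) - 1), 0.1)
})

test_that("global Schoenfeld test calibrates under proportional hazards", {
  set.seed(99)
  rejected <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    x <- rnorm(80)
    tm <- rexp(80, rate = exp(0.5 * x))
    fit <- survival::coxph(survival::Surv(tm, rep(1, 80)) ~ x)
    if (schoenfeldGlobalTest(fit) < 0.05) rejected <- rejected + 1
  }
  expect_gt(rejected / reps, 0.02)
  expect_lt(rejected / reps, 0.09)
})

test_that("global Schoenfeld test detects a sign-flipping effect", {
  set.seed(17)
  rejections <- 0
  for (i in 1:10) {
    n <- 200
    x <- rnorm(n)
    t0 <- log(2)                       # effect reverses at the median
    early <- rexp(n, rate = exp(1.5 * x))
    late <- t0 + rexp(n, rate = exp(-1.5 * x))
    tm <- ifelse(early < t0, early, late)
    fit <- survival::coxph(survival::Surv(tm, rep(1, n)) ~ x)
    if (schoenfeldGlobalTest(fit) < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 8)
})

test_that("with one covariate the global test equals the covariate test", {
  set.seed(23)
  x <- rnorm(60)
  tm <- rexp(60, rate = exp(0.5 * x))
  fit <- survival::coxph(survival::Surv(tm, rep(1, 60)) ~ x)
  zp <- survival::cox.zph(fit, transform = "km")
  expect_equal(schoenfeldGlobalTest(fit), zp$table["x", "p"],
               tolerance = 1e-12)
})

test_that("few events relative to covariates triggers a warning", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 0, 0, 0, 0, 0)
  w <- capture_warnings(coxFit(tm, ev, data.frame(a = rnorm(6), b = rnorm(6))))
  expect_match(w, "fewer events than covariates", all = FALSE)
})
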