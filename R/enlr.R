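# Cost-sensitive elastic-net penalized logistic regression of ICB response
# on pair scores: prior-probability offset, stratified 5-fold CV over AUC.

#' Prior-probability offset for cost-sensitive fitting
#'
#' The class imbalance correction enters the logistic model as a constant
#' offset on the log-odds scale, computed from the empirical responder
#' frequency and a predefined classification threshold tau:
#' \deqn{o = logit(\hat\pi) - logit(\tau), \quad \hat\pi = n_R/(n_R+n_{NR})}
#' With minority responders and tau = 2/3 the offset is negative; fitting
#' with it and predicting without it shifts predicted probabilities upward,
#' weighting the minority class without resampling the data.
#'
#' @param nResponders,nNonResponders positive class counts.
#' @param tau classification threshold in (0, 1), default 2/3.
#' @return the offset (single numeric).
#' @export
computeOffset <- function(nResponders, nNonResponders, tau = 2 / 3) {
  if (nResponders <= 0 || nNonResponders <= 0)
    stop("cannot fit with a single class (zero count in R or NR)")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  pihat <- nResponders / (nResponders + nNonResponders)
  log(pihat / (1 - pihat)) - log(tau / (1 - tau))
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently and deals fold labels in round-robin,
#' so per-fold class proportions deviate from the global proportions by at
#' most one sample. Deterministic given the seed.
#'
#' @param labels character/factor class labels.
#' @param nFolds number of folds, default 5.
#' @param seed integer RNG seed.
#' @return integer fold id (1..nFolds) per sample.
#' @export
stratifiedFolds <- function(labels, nFolds = 5, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (nFolds > n) stop("more folds than samples")
  if (nFolds < 2L) stop("need at least 2 folds")
  counts <- table(labels)
  if (any(counts < nFolds))
    warning("class(es) with fewer samples than folds: ",
            paste(names(counts)[counts < nFolds], collapse = ", "),
            "; some folds will miss a class")
  fold <- integer(n)
  .withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

# AUC of linear predictors against R/NR labels by the rank (Mann-Whitney,
# half credit for ties) identity; internal, label-safe for fold use.
.aucOf <- function(score, labels) {
  pos <- labels == "R"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Fit the cost-sensitive elastic-net logistic regression
#'
#' Minimizes the penalized negative binomial log-likelihood
#' \deqn{-\frac{1}{n}\sum_i [y_i \eta_i - \log(1+e^{\eta_i})] +
#'   \lambda(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2)}
#' with \eqn{\eta_i = \beta_0 + o + \sum_j \beta_j x_{ij}} via
#' \code{glmnet}, where o is the prior-probability offset from
#' [computeOffset()]. The lambda grid is 100 log-spaced values from the
#' data-derived lambda_max down to 0.001 lambda_max; lambda is selected to
#' maximize the mean held-out AUC over stratified folds. Because AUC is a
#' rank statistic that saturates under strong separation, exact ties along
#' the grid are broken by the parsimony-adjusted held-out deviance (mean CV
#' binomial deviance plus an AIC-type penalty of 2 df/n), and remaining
#' ties toward the largest lambda (sparser model). The final coefficients
#' come from the full-data path fit at the selected lambda, reported on the
#' original score scale.
#'
#' Samples labelled "unknown" are excluded from fitting. Zero-variance
#' features are dropped with a warning (reported with coefficient 0).
#'
#' @param scoreMatrix a [PairScoreMatrix-class] or pairs-by-samples matrix.
#' @param labels response per sample ("R"/"NR"/"unknown"), aligned with the
#'   score matrix columns.
#' @param alpha elastic-net mixing in [0, 1], default 0.5.
#' @param nFolds CV folds, default 5.
#' @param tau threshold behind the offset, default 2/3.
#' @param standardize standardize features internally before penalization
#'   (coefficients are still reported on the original scale), default TRUE.
#' @param seed integer seed for the fold assignment.
#' @param nLambda,lambdaMinRatio lambda grid size and lower end relative to
#'   lambda_max.
#' @return an [EnlrFit-class].
#' @export
fitEnlr <- function(scoreMatrix, labels, alpha = 0.5, nFolds = 5,
                    tau = 2 / 3, standardize = TRUE, seed = 1,
                    nLambda = 100, lambdaMinRatio = 0.001) {
  s <- if (is(scoreMatrix, "PairScoreMatrix")) scores(scoreMatrix)
       else scoreMatrix
  if (is.null(rownames(s))) stop("score matrix must have pair rownames")
  labels <- as.character(labels)
  if (length(labels) != ncol(s))
    stop("labels must align with score matrix columns")
  use <- labels %in% c("R", "NR")
  if (sum(!use))
    message("excluding ", sum(!use), " sample(s) with unknown response")
  x <- t(s[, use, drop = FALSE])
  y <- factor(labels[use], levels = c("NR", "R"))
  counts <- table(y)
  if (any(counts < 2L)) stop("need at least 2 samples per class")
  keepVar <- apply(x, 2L, function(col) var(col) > 0)
  if (any(!keepVar))
    warning("dropping ", sum(!keepVar), " zero-variance feature(s): ",
            paste(colnames(x)[!keepVar], collapse = ", "))
  xUse <- x[, keepVar, drop = FALSE]
  if (ncol(xUse) < 2L)
    stop("need at least 2 non-degenerate features to fit the penalized model")
  o <- computeOffset(counts[["R"]], counts[["NR"]], tau)
  offs <- rep(o, nrow(xUse))

  full <- glmnet::glmnet(xUse, y, family = "binomial", alpha = alpha,
                         offset = offs, standardize = standardize,
                         nlambda = nLambda,
                         lambda.min.ratio = lambdaMinRatio,
                         thresh = 1e-10)
  lambda <- full$lambda

  foldid <- stratifiedFolds(as.character(y), nFolds = nFolds, seed = seed)
  aucs <- devs <- matrix(NA_real_, nFolds, length(lambda))
  for (k in seq_len(nFolds)) {
    hold <- foldid == k
    fitK <- glmnet::glmnet(xUse[!hold, , drop = FALSE], y[!hold],
                           family = "binomial", alpha = alpha,
                           offset = offs[!hold], lambda = lambda,
                           standardize = standardize, thresh = 1e-10)
    eta <- predict(fitK, xUse[hold, , drop = FALSE],
                   newoffset = offs[hold], type = "link")
    yHold <- as.integer(y[hold] == "R")
    aucs[k, ] <- apply(eta, 2L, .aucOf, labels = as.character(y)[hold])
    devs[k, ] <- apply(eta, 2L, function(e)
      mean(-2 * (yHold * e - log1p(exp(e)))))
  }
  cvm <- colMeans(aucs, na.rm = TRUE)
  cvsd <- apply(aucs, 2L, sd, na.rm = TRUE)
  cvdev <- colMeans(devs, na.rm = TRUE)
  # AUC is a rank statistic and saturates under strong separation, leaving
  # long runs of exactly tied lambda values; ties are broken by the
  # parsimony-adjusted held-out deviance (mean CV binomial deviance plus an
  # AIC-type complexity penalty 2*df/n), remaining ties toward the largest
  # lambda (sparser model). lambda is stored in decreasing order, so the
  # first index wins remaining ties.
  tie <- which(cvm >= max(cvm, na.rm = TRUE) - 1e-10)
  crit <- cvdev[tie] + 2 * full$df[tie] / nrow(xUse)
  best <- tie[which(crit <= min(crit) + 1e-12)[1L]]
  lambdaOpt <- lambda[best]

  beta <- drop(as.matrix(coef(full, s = lambdaOpt, exact = FALSE)))
  intercept <- beta[["(Intercept)"]]
  coefs <- setNames(numeric(nrow(s)), rownames(s))
  fitted <- beta[-1L]
  coefs[names(fitted)] <- fitted

  new("EnlrFit",
      intercept = intercept,
      coefficients = coefs,
      offset = o,
      lambdaOpt = lambdaOpt,
      alpha = alpha,
      tau = tau,
      cvCurve = data.frame(lambda = lambda, aucMean = cvm, aucSD = cvsd,
                           devMean = cvdev),
      classCounts = c(NR = as.integer(counts[["NR"]]),
                      R = as.integer(counts[["R"]])),
      standardize = standardize,
      seed = as.integer(seed),
      path = full)
}

#' Coefficients of the fitted path at an arbitrary grid lambda
#'
#' @param fit an [EnlrFit-class].
#' @param lambda a value on (or near) the fitted lambda grid.
#' @return named numeric vector: intercept followed by feature coefficients.
#' @export
coefAtLambda <- function(fit, lambda) {
  stopifnot(is(fit, "EnlrFit"))
  drop(as.matrix(coef(fit@path, s = lambda, exact = FALSE)))
}
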