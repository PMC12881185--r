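# The LRPS signature: effect-size-weighted average of selected pair scores,
# per-sample odds ratios, Youden threshold, high/low stratification.

.pairScoresFor <- function(s, pairs) {
  if (is(s, "PairScoreMatrix")) s <- scores(s)
  if (is.null(dim(s))) s <- matrix(s, ncol = 1, dimnames = list(names(s), "sample"))
  missing <- setdiff(pairs, rownames(s))
  if (length(missing))
    stop("score matrix lacks selected pair(s): ",
         paste(missing, collapse = ", "))
  s[pairs, , drop = FALSE]
}

#' Ligand-receptor pair signature score (LRPS)
#'
#' The weighted average of the selected pairs' enrichment scores, using the
#' elastic-net effect sizes as weights:
#' \deqn{LRPS = \sum_j w_j s_j / \sum_j |w_j|}
#' The absolute-value denominator keeps the score stable under negative
#' effect sizes and invariant to rescaling all weights by a positive
#' constant.
#'
#' @param signature an [LRSignature-class] (or [EnlrFit-class]).
#' @param scoreMatrix a [PairScoreMatrix-class], pairs-by-samples matrix,
#'   or a named per-pair score vector for one sample. Missing selected
#'   pairs are an error (no silent imputation).
#' @return named numeric LRPS per sample.
#' @export
lrps <- function(signature, scoreMatrix) {
  w <- effectSizes(signature)
  if (length(w) == 0L) stop("empty signature: no selected pairs")
  s <- .pairScoresFor(scoreMatrix, names(w))
  drop(colSums(s * w) / sum(abs(w)))
}

#' Per-sample predicted probability and odds ratio
#'
#' Computes the linear predictor \eqn{\eta = \beta_0 + \sum_j \beta_j s_j}
#' of the fitted logistic model, the predicted response probability
#' \eqn{1/(1+e^{-\eta})} and the per-sample odds \eqn{e^{\eta}} (the odds
#' ratio relative to even odds). By default the prior-probability offset
#' used during fitting is \emph{not} added back, so the cost-sensitive
#' correction shifts probabilities toward the minority class;
#' \code{includeOffset = TRUE} retains it instead. \code{orType =
#' "centered"} returns \eqn{e^{\eta - \bar\eta}} (odds relative to the
#' cohort mean linear predictor).
#'
#' @param object an [LRSignature-class] or [EnlrFit-class].
#' @param scoreMatrix scores as in [lrps()].
#' @param includeOffset add the training offset to the linear predictor.
#' @param orType "odds" (default) or "centered".
#' @return data.frame: sample_id, eta, prob, odds_ratio.
#' @export
sampleOdds <- function(object, scoreMatrix, includeOffset = FALSE,
                       orType = c("odds", "centered")) {
  orType <- match.arg(orType)
  w <- effectSizes(object)
  b0 <- object@intercept
  o <- object@offset
  if (length(w)) {
    s <- .pairScoresFor(scoreMatrix, names(w))
    eta <- b0 + drop(colSums(s * w))
  } else {
    s <- if (is(scoreMatrix, "PairScoreMatrix")) scores(scoreMatrix)
         else scoreMatrix
    eta <- rep(b0, if (is.null(dim(s))) 1L else ncol(s))
    names(eta) <- if (is.null(dim(s))) "sample" else colnames(s)
  }
  if (includeOffset) eta <- eta + o
  orVal <- if (orType == "centered") exp(eta - mean(eta)) else exp(eta)
  data.frame(sample_id = names(eta), eta = unname(eta),
             prob = unname(plogis(eta)), odds_ratio = unname(orVal),
             stringsAsFactors = FALSE)
}

#' Youden-index probability threshold
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' probabilities, plus sentinels below the minimum and above the maximum)
#' and returns the one maximizing J = sensitivity + specificity - 1 for the
#' call "R iff prob >= threshold". Ties are broken toward the smallest
#' threshold.
#'
#' @param probs predicted probabilities.
#' @param labels "R"/"NR" per sample (both classes required).
#' @return the threshold (numeric).
#' @export
youdenThreshold <- function(probs, labels) {
  labels <- as.character(labels)
  pos <- labels == "R"
  if (!any(pos) || all(pos))
    stop("need both classes to compute the Youden threshold")
  u <- sort(unique(probs))
  lo <- if (u[1L] > 0) u[1L] / 2 else u[1L] - 1
  hi <- if (u[length(u)] < 1) (u[length(u)] + 1) / 2 else u[length(u)] + 1
  cand <- c(lo, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, hi)
  j <- vapply(cand, function(th) {
    calls <- probs >= th
    sens <- sum(calls & pos) / sum(pos)
    spec <- sum(!calls & !pos) / sum(!pos)
    sens + spec - 1
  }, numeric(1))
  cand[which(j >= max(j) - 1e-12)[1L]]
}

#' Split samples into high and low odds-ratio groups
#'
#' "high" includes equality with the cutoff (all samples are "high" when
#' every odds ratio equals the cutoff). The cutoff convention is the
#' arithmetic mean of the cohort's per-sample odds ratios.
#'
#' @param oddsRatios numeric per-sample odds ratios.
#' @param orCutoff the cutoff; defaults to \code{mean(oddsRatios)}.
#' @return character vector over {"high", "low"}.
#' @export
assignGroups <- function(oddsRatios, orCutoff = mean(oddsRatios)) {
  ifelse(oddsRatios >= orCutoff, "high", "low")
}

#' Freeze a fitted model into a portable signature
#'
#' Attaches to the elastic-net fit everything needed to score new cohorts:
#' the selected pairs with their gene sets and effect sizes, the scoring
#' settings, the Youden probability threshold computed on the training
#' samples, and the mean training odds ratio as the high/low cutoff.
#'
#' @param fit an [EnlrFit-class].
#' @param scoreMatrix the training [PairScoreMatrix-class].
#' @param labels training labels ("R"/"NR"/"unknown") aligned with the
#'   score matrix columns; unknowns are ignored for the thresholds.
#' @param catalog the [LRPairCatalog-class] the scores were computed from.
#' @param includeOffset forwarding of the [sampleOdds()] convention.
#' @return an [LRSignature-class].
#' @export
buildSignature <- function(fit, scoreMatrix, labels, catalog,
                           includeOffset = FALSE) {
  stopifnot(is(fit, "EnlrFit"), is(catalog, "LRPairCatalog"))
  labels <- as.character(labels)
  sel <- selectedPairs(fit)
  if (length(sel) == 0L)
    warning("no pairs selected at the optimal lambda; ",
            "the signature is degenerate (intercept-only)")
  gs <- geneSets(catalog)
  missing <- setdiff(sel, names(gs))
  if (length(missing))
    stop("catalog lacks selected pair(s): ", paste(missing, collapse = ", "))
  odds <- sampleOdds(fit, scoreMatrix, includeOffset = includeOffset)
  use <- labels %in% c("R", "NR")
  theta <- youdenThreshold(odds$prob[use], labels[use])
  exponent <- if (is(scoreMatrix, "PairScoreMatrix"))
    scoreMatrix@exponent else NA_real_
  normalization <- if (is(scoreMatrix, "PairScoreMatrix"))
    scoreMatrix@normalization else "raw"
  new("LRSignature",
      selectedPairs = sel,
      effectSizes = effectSizes(fit),
      geneSets = gs[sel],
      intercept = fit@intercept,
      offset = fit@offset,
      lambdaOpt = fit@lambdaOpt,
      alpha = fit@alpha,
      tau = fit@tau,
      exponent = exponent,
      normalization = normalization,
      youdenThreshold = theta,
      orCutoff = mean(odds$odds_ratio),
      provenance = list(
        package = "lrpsig",
        version = as.character(utils::packageVersion("lrpsig")),
        seed = fit@seed,
        classCounts = as.list(fit@classCounts),
        catalogPairs = pairIds(catalog),
        includeOffset = includeOffset))
}

#' Assess every sample against a frozen signature
#'
#' Computes LRPS, predicted probability, per-sample odds ratio, the
#' response call (R iff prob >= the signature's Youden threshold) and the
#' high/low group. By default the high/low cutoff is recomputed as the mean
#' odds ratio of the cohort being assessed; \code{orCutoff = "training"}
#' reuses the cutoff frozen from the training cohort instead.
#'
#' @param signature an [LRSignature-class].
#' @param scoreMatrix a [PairScoreMatrix-class] or pairs-by-samples matrix
#'   covering all selected pairs.
#' @param orCutoff "cohort" (default) or "training".
#' @param includeOffset forwarding of the [sampleOdds()] convention; by
#'   default the convention stored in the signature's provenance is used.
#' @return data.frame: sample_id, lrps, prob, odds_ratio, group,
#'   response_call.
#' @export
assessSamples <- function(signature, scoreMatrix,
                          orCutoff = c("cohort", "training"),
                          includeOffset = NULL) {
  stopifnot(is(signature, "LRSignature"))
  orCutoff <- match.arg(orCutoff)
  if (is.null(includeOffset))
    includeOffset <- isTRUE(signature@provenance$includeOffset)
  score <- lrps(signature, scoreMatrix)
  odds <- sampleOdds(signature, scoreMatrix, includeOffset = includeOffset)
  cut <- if (orCutoff == "training") signature@orCutoff
         else mean(odds$odds_ratio)
  data.frame(
    sample_id = odds$sample_id,
    lrps = unname(score[odds$sample_id]),
    prob = odds$prob,
    odds_ratio = odds$odds_ratio,
    group = assignGroups(odds$odds_ratio, cut),
    response_call = ifelse(odds$prob >= signature@youdenThreshold,
                           "R", "NR"),
    stringsAsFactors = FALSE)
}
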