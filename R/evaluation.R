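# Discrimination and association metrics: ROC/AUC, confusion matrix,
# response rates, one-tailed rank test, chi-square association.

#' ROC curve and AUC
#'
#' The AUC is computed by the Mann-Whitney identity (ties receive half
#' credit), which coincides with trapezoidal integration of the empirical
#' ROC. The curve enumerates all calls "R iff score >= threshold" over the
#' unique scores plus sentinels.
#'
#' @param score numeric scores (higher = more responder-like).
#' @param labels "R"/"NR" per sample; both classes required.
#' @return list of class "RocCurve": thresholds, sensitivity, specificity,
#'   auc.
#' @export
rocAuc <- function(score, labels) {
  labels <- as.character(labels)
  pos <- labels == "R"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("need both classes for a ROC curve")
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  u <- sort(unique(score))
  thresholds <- c(-Inf, u, Inf)
  sens <- vapply(thresholds, function(th) sum(pos & score >= th) / nP,
                 numeric(1))
  spec <- vapply(thresholds, function(th) sum(!pos & score < th) / nN,
                 numeric(1))
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc),
            class = "RocCurve")
}

#' @export
print.RocCurve <- function(x, ...) {
  cat(sprintf("ROC curve over %d thresholds; AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Confusion-matrix metrics for the response call
#'
#' Positive class is "R". Precision and F1 are reported as NA when no
#' positive call was made (tp + fp = 0).
#'
#' @param calls predicted labels ("R"/"NR").
#' @param labels true labels ("R"/"NR").
#' @return list of class "ConfusionMetrics": tp, fp, tn, fn, precision,
#'   recall, specificity, accuracy, f1.
#' @export
confusionMetrics <- function(calls, labels) {
  calls <- as.character(calls); labels <- as.character(labels)
  if (length(calls) != length(labels))
    stop("calls and labels must have equal length")
  tp <- sum(calls == "R" & labels == "R")
  fp <- sum(calls == "R" & labels == "NR")
  tn <- sum(calls == "NR" & labels == "NR")
  fn <- sum(calls == "NR" & labels == "R")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  accuracy <- (tp + tn) / length(calls)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall,
                 specificity = specificity, accuracy = accuracy, f1 = f1),
            class = "ConfusionMetrics")
}

#' @export
print.ConfusionMetrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("precision=%.3f recall=%.3f specificity=%.3f accuracy=%.3f f1=%.3f\n",
              x$precision, x$recall, x$specificity, x$accuracy, x$f1))
  invisible(x)
}

#' Responder rate per high/low group
#'
#' @param groups "high"/"low" per sample.
#' @param labels "R"/"NR" per sample.
#' @return data.frame: group, n, responders, rate (fraction), plus an
#'   attribute "difference" (high rate minus low rate).
#' @export
responseRates <- function(groups, labels) {
  groups <- as.character(groups); labels <- as.character(labels)
  out <- do.call(rbind, lapply(c("high", "low"), function(g) {
    n <- sum(groups == g)
    r <- sum(groups == g & labels == "R")
    if (n == 0L) {
      warning("empty group '", g, "'; rate reported as NA")
      rate <- NA_real_
    } else rate <- r / n
    data.frame(group = g, n = n, responders = r, rate = rate,
               stringsAsFactors = FALSE)
  }))
  attr(out, "difference") <- out$rate[out$group == "high"] -
    out$rate[out$group == "low"]
  out
}

#' One-tailed Wilcoxon rank-sum test (responders greater)
#'
#' Tests whether responder scores are stochastically greater than
#' non-responder scores. The p-value is exact (enumeration) when the
#' combined sample has at most 12 observations and no ties, and otherwise
#' uses the normal approximation with tie and continuity correction.
#'
#' @param x scores of the R group.
#' @param y scores of the NR group.
#' @return list: statistic (Mann-Whitney U of x), p.value, exact (logical).
#' @export
wilcoxonOneTailed <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater",
                       exact = useExact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = useExact)
}

#' Chi-square association of the signature group with a clinical variable
#'
#' Pearson chi-square on the group-by-variable contingency table, without
#' continuity correction by default (set \code{yates = TRUE} for the
#' corrected 2x2 test). A zero row or column margin is an error; expected
#' counts below 5 trigger a warning.
#'
#' @param groups "high"/"low" (or any categorical) per sample.
#' @param clinicalVar categorical clinical variable per sample.
#' @param yates apply Yates continuity correction (2x2 only).
#' @return list: statistic, df, p.value, table, expected.
#' @export
chiSquareAssociation <- function(groups, clinicalVar, yates = FALSE) {
  tab <- table(group = as.character(groups),
               variable = as.character(clinicalVar))
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("contingency table has a zero margin (a group or category is absent)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  if (any(ct$expected < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab, expected = ct$expected)
}

#' Evaluate assessments against true labels
#'
#' Convenience bundle: AUC of the predicted probability, confusion metrics
#' both at the Youden call and at the high/low grouping, per-group response
#' rates, and the one-tailed rank test on LRPS (R greater).
#'
#' @param assessments data.frame from [assessSamples()].
#' @param labels true labels aligned with assessments ("R"/"NR"/"unknown";
#'   unknowns are dropped).
#' @return list: auc, roc, confusionYouden, confusionGroup, responseRates,
#'   wilcoxonLrps.
#' @export
evaluateAssessments <- function(assessments, labels) {
  labels <- as.character(labels)
  use <- labels %in% c("R", "NR")
  a <- assessments[use, , drop = FALSE]
  l <- labels[use]
  roc <- rocAuc(a$prob, l)
  list(
    auc = roc$auc,
    roc = roc,
    confusionYouden = confusionMetrics(a$response_call, l),
    confusionGroup = confusionMetrics(
      ifelse(a$group == "high", "R", "NR"), l),
    responseRates = responseRates(a$group, l),
    wilcoxonLrps = wilcoxonOneTailed(a$lrps[l == "R"], a$lrps[l == "NR"])
  )
}
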