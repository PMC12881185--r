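# End-to-end orchestration: score -> train -> predict -> evaluate ->
# survival on a training cohort, and frozen-signature validation.

.matchSamples <- function(expr, clinical) {
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) < 4L)
    stop("fewer than 4 samples shared between expression and clinical")
  dropped <- (ncol(expr) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0)
    message("dropped ", dropped,
            " sample(s) unmatched between expression and clinical tables")
  list(expr = expr[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample_id), ,
                           drop = FALSE])
}

.survivalSummary <- function(assessments, clinical, endpoint = "pfs") {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical))) return(NULL)
  ok <- !is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]])
  tm <- clinical[[tcol]][ok]; ev <- clinical[[ecol]][ok]
  grp <- assessments$group[ok]
  lrpsv <- assessments$lrps[ok]
  out <- list(endpoint = endpoint)
  if (length(unique(grp)) == 2L) {
    out$logrank <- logrankTest(tm, ev, grp)
    cf <- coxFit(tm, ev,
                 data.frame(group = factor(grp, levels = c("low", "high"))))
    out$coxGroup <- cf
    out$hrHighVsLow <- cf$table$hr[cf$table$term == "grouphigh"]
  }
  out$coxLrps <- tryCatch(coxFit(tm, ev, data.frame(lrps = lrpsv)),
                          error = function(e) NULL)
  out$kmByGroup <- lapply(split(seq_along(tm), grp), function(i)
    kmEstimate(tm[i], ev[i]))
  out
}

#' Train the LRPS signature on a cohort
#'
#' Runs the full construction pipeline: ssGSEA pair scoring, cost-sensitive
#' elastic-net logistic fit with 5-fold CV over AUC, Youden thresholding
#' and mean-OR stratification, then evaluation and survival analyses on the
#' training cohort. When \code{outDir} is given, persists model.json,
#' assessments.tsv, pair_scores.tsv, cv_curve.tsv and the resolved
#' configuration.
#'
#' @param expr genes-by-samples TPM matrix ([readExpression()]).
#' @param clinical clinical data.frame ([readClinical()]).
#' @param catalog an [LRPairCatalog-class].
#' @param wExp,normalize ssGSEA settings (see [scorePairs()]).
#' @param alpha,tau,nFolds elastic-net settings (see [fitEnlr()]).
#' @param seed integer seed (fold assignment).
#' @param outDir optional output directory.
#' @return list: fit, signature, scores, assessments, metrics, survival.
#' @export
runTrainPipeline <- function(expr, clinical, catalog, wExp = 0.25,
                             normalize = c("raw", "range"), alpha = 0.5,
                             tau = 2 / 3, nFolds = 5, seed = 1,
                             outDir = NULL) {
  normalize <- match.arg(normalize)
  m <- .matchSamples(expr, clinical)
  sm <- scorePairs(m$expr, catalog, wExp = wExp, normalize = normalize)
  labels <- m$clinical$response
  fit <- fitEnlr(sm, labels, alpha = alpha, tau = tau, nFolds = nFolds,
                 seed = seed)
  signature <- buildSignature(fit, sm, labels, catalog)
  assessments <- assessSamples(signature, sm)
  metrics <- evaluateAssessments(assessments, labels)
  surv <- list(pfs = .survivalSummary(assessments, m$clinical, "pfs"),
               os = .survivalSummary(assessments, m$clinical, "os"))
  res <- list(fit = fit, signature = signature, scores = sm,
              assessments = assessments, metrics = metrics,
              survival = surv)
  if (!is.null(outDir)) .persistRun(res, m$clinical, outDir, seed)
  res
}

#' Validate a frozen signature on an independent cohort
#'
#' Scores the cohort with the signature's own gene sets and settings; the
#' signature, its Youden threshold and its effect sizes are never refit.
#' Selected pairs whose member genes are all absent from the validation
#' matrix are an error (no silent imputation). The high/low cutoff is the
#' validation cohort's own mean odds ratio by default
#' (\code{orCutoff = "training"} reuses the frozen training cutoff).
#'
#' @param expr,clinical validation cohort inputs.
#' @param signature an [LRSignature-class] (e.g. from [readModel()]).
#' @param orCutoff "cohort" (default) or "training".
#' @param outDir optional output directory.
#' @return list: scores, assessments, metrics, survival.
#' @export
runValidatePipeline <- function(expr, clinical, signature,
                                orCutoff = c("cohort", "training"),
                                outDir = NULL) {
  orCutoff <- match.arg(orCutoff)
  stopifnot(is(signature, "LRSignature"))
  if (length(signature@selectedPairs) == 0L)
    stop("empty signature: no selected pairs to validate")
  m <- .matchSamples(expr, clinical)
  gs <- geneSets(signature)
  measured <- vapply(gs, function(g) length(intersect(g, rownames(m$expr))),
                     integer(1))
  if (any(measured == 0L)) {
    bad <- names(gs)[measured == 0L]
    stop("selected pair(s) with no measured genes in validation matrix: ",
         paste(sprintf("%s (genes %s)", bad,
                       vapply(gs[bad], paste, "", collapse = ",")),
               collapse = "; "))
  }
  sm <- scorePairs(m$expr, gs, wExp = signature@exponent,
                   normalize = signature@normalization)
  assessments <- assessSamples(signature, sm, orCutoff = orCutoff)
  labels <- m$clinical$response
  metrics <- if (length(unique(labels[labels %in% c("R", "NR")])) == 2L)
    evaluateAssessments(assessments, labels) else NULL
  surv <- list(pfs = .survivalSummary(assessments, m$clinical, "pfs"),
               os = .survivalSummary(assessments, m$clinical, "os"))
  res <- list(scores = sm, assessments = assessments, metrics = metrics,
              survival = surv)
  if (!is.null(outDir)) .persistRun(res, m$clinical, outDir, seed = NA)
  res
}

.persistRun <- function(res, clinical, outDir, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$signature))
    writeModel(res$signature, file.path(outDir, "model.json"))
  utils::write.table(res$assessments, file.path(outDir, "assessments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- scores(res$scores)
  utils::write.table(data.frame(pair = rownames(sm), sm,
                                check.names = FALSE),
                     file.path(outDir, "pair_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$fit))
    utils::write.table(res$fit@cvCurve, file.path(outDir, "cv_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "lrpsig",
    version = as.character(utils::packageVersion("lrpsig")),
    seed = if (is.na(seed)) NULL else seed,
    nSamples = nrow(clinical),
    classCounts = as.list(table(clinical$response)),
    outputs = c("model.json", "assessments.tsv", "pair_scores.tsv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
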