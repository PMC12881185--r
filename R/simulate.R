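# Synthetic on-treatment cohorts with planted ligand-receptor signal and
# score-linked censored survival, for end-to-end testing without patient
# data. Emulates the structure of small ICB melanoma cohorts: TPM-scale
# log-normal expression, a minority/majority responder split, a few
# informative pairs whose member genes shift in responders, and exponential
# survival whose hazard decreases with the latent signal.

.PAPER_PAIRS <- data.frame(
  ligand = c("FLT3", "LY9", "CD5", "CD40LG", "APP", "TNFRSF17", "FCER2"),
  receptor = c("FLT3LG", "LY9", "CD5", "ITGA2B/ITGB3", "CD74", "TNFSF13",
               "ITGAV/ITGB3"),
  stringsAsFactors = FALSE)

#' Default ligand-receptor catalog for simulations
#'
#' Returns the seven signature pairs reported for ICB response in
#' metastatic melanoma (FLT3-FLT3LG, LY9-LY9, CD5-CD5,
#' CD40LG-ITGA2B/ITGB3, APP-CD74, TNFRSF17-TNFSF13, FCER2-ITGAV/ITGB3)
#' padded with synthetic pairs over invented gene symbols (LGxxx/RCxxx,
#' every fifth receptor a two-subunit complex), disjoint from the
#' simulator's background genes (BGxxxx).
#'
#' @param nPairs total number of pairs, at least 7.
#' @param nBackgroundGenes number of background genes the simulator will
#'   add; recorded for bookkeeping (synthetic pair symbols never collide
#'   with background symbols by construction).
#' @param seed integer seed (controls which synthetic receptors are
#'   complexes).
#' @return an [LRPairCatalog-class].
#' @export
makeDefaultCatalog <- function(nPairs = 40, nBackgroundGenes = 0, seed = 1) {
  if (nPairs < 7L) stop("nPairs must be at least 7 (the named signature pairs)")
  if (nBackgroundGenes < 0) stop("nBackgroundGenes must be non-negative")
  lig <- .PAPER_PAIRS$ligand
  rec <- .PAPER_PAIRS$receptor
  nExtra <- nPairs - 7L
  if (nExtra > 0L) {
    isComplex <- .withSeed(seed, sample(seq_len(nExtra)) %% 5L == 0L)
    extraLig <- sprintf("LG%03d", seq_len(nExtra))
    extraRec <- sprintf("RC%03d", seq_len(nExtra))
    extraRec[isComplex] <- paste0(extraRec[isComplex], "/",
                                  sprintf("RC%03dB", which(isComplex)))
    lig <- c(lig, extraLig)
    rec <- c(rec, extraRec)
  }
  makeLRPairCatalog(lig, rec)
}

#' Assemble and validate a simulation configuration
#'
#' Defaults emulate a Riaz-like training cohort: 54 on-treatment samples
#' with a 21/54 responder fraction, day-scale exponential PFS/OS with a
#' median around 140 days at the baseline hazard, and ~20% independent
#' censoring.
#'
#' @param nSamples cohort size.
#' @param responderFraction fraction of responders in (0, 1).
#' @param nGenes total genes in the matrix (catalog genes plus invented
#'   background genes).
#' @param catalog an [LRPairCatalog-class].
#' @param informativePairs pair ids whose member genes shift in responders.
#' @param delta log2-TPM shift added to informative-pair member genes in
#'   responders (>= 0).
#' @param noiseSd standard deviation of log2 expression (> 0).
#' @param baselineMu baseline mean of log2 expression.
#' @param hazardBase baseline exponential hazard per day (> 0).
#' @param hazardCoef log-hazard decrease per unit of the standardized
#'   latent signal (gamma; larger means high-signal samples live longer).
#' @param censorRate target fraction of independently censored samples in
#'   [0, 1).
#' @param seed integer master seed.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(nSamples = 54,
                             responderFraction = 21 / 54,
                             nGenes = 500,
                             catalog = makeDefaultCatalog(40),
                             informativePairs = pairIds(catalog)[1:5],
                             delta = 1,
                             noiseSd = 1,
                             baselineMu = 3,
                             hazardBase = 0.005,
                             hazardCoef = 1,
                             censorRate = 0.2,
                             seed = 1) {
  stopifnot(is(catalog, "LRPairCatalog"))
  if (nSamples < 4L) stop("nSamples must be at least 4")
  if (responderFraction <= 0 || responderFraction >= 1)
    stop("responderFraction must lie in (0, 1)")
  if (delta < 0) stop("delta must be non-negative")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (hazardBase <= 0) stop("hazardBase must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  missing <- setdiff(informativePairs, pairIds(catalog))
  if (length(missing))
    stop("informative pair(s) absent from catalog: ",
         paste(missing, collapse = ", "))
  catGenes <- unique(unlist(geneSets(catalog)))
  if (nGenes < length(catGenes))
    stop("nGenes must cover at least the ", length(catGenes),
         " catalog genes")
  structure(list(nSamples = as.integer(nSamples),
                 responderFraction = responderFraction,
                 nGenes = as.integer(nGenes),
                 catalog = catalog,
                 informativePairs = informativePairs,
                 delta = delta, noiseSd = noiseSd, baselineMu = baselineMu,
                 hazardBase = hazardBase, hazardCoef = hazardCoef,
                 censorRate = censorRate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate an on-treatment cohort with planted signal
#'
#' Log2 expression is Normal(baselineMu, noiseSd) per gene and sample,
#' exponentiated to the TPM scale. In responders, every member gene of the
#' informative pairs is shifted by +delta on the log2 scale. The latent
#' signal z of a sample is the standardized mean log2 expression of the
#' shifted genes. PFS and OS are exponential with rate
#' hazardBase * exp(-hazardCoef * z) (OS at 60\% of the PFS hazard), with
#' independent exponential censoring calibrated to the target censoring
#' fraction. Response labels are assigned by design (random sampling of
#' responder positions), not by thresholding z, so the classification task
#' stays genuinely noisy. Bit-for-bit reproducible from (config, seed).
#'
#' @param config a [simulationConfig()] list.
#' @return a \code{SummarizedExperiment}: assay "tpm", clinical columns in
#'   \code{colData}, and \code{metadata(x)$truth} holding the informative
#'   pairs, per-sample latent signal z, and responder ids.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  sub <- .subSeeds(config$seed, 5L)
  n <- config$nSamples
  sampleIds <- sprintf("S%04d", seq_len(n))
  catGenes <- unique(unlist(geneSets(config$catalog)))
  nBg <- config$nGenes - length(catGenes)
  genes <- c(catGenes, if (nBg > 0) sprintf("BG%04d", seq_len(nBg)))

  nR <- round(n * config$responderFraction)
  if (nR < 1L || nR >= n)
    stop("responderFraction leaves an empty class at this nSamples")
  respIdx <- .withSeed(sub[1L], sort(sample(n, nR)))
  response <- rep("NR", n)
  response[respIdx] <- "R"

  logE <- .withSeed(sub[2L],
    matrix(rnorm(length(genes) * n, config$baselineMu, config$noiseSd),
           nrow = length(genes), ncol = n,
           dimnames = list(genes, sampleIds)))
  shiftGenes <- unique(unlist(geneSets(config$catalog)[
    config$informativePairs]))
  logE[shiftGenes, respIdx] <- logE[shiftGenes, respIdx] + config$delta

  zRaw <- colMeans(logE[shiftGenes, , drop = FALSE])
  z <- if (sd(zRaw) > 0) (zRaw - mean(zRaw)) / sd(zRaw) else zRaw * 0

  rate <- config$hazardBase * exp(-config$hazardCoef * z)
  surv <- .withSeed(sub[3L], {
    list(pfs = rexp(n, rate), os = rexp(n, rate * 0.6))
  })
  if (config$censorRate > 0) {
    cRatePfs <- config$hazardBase *
      config$censorRate / (1 - config$censorRate)
    cens <- .withSeed(sub[4L], {
      list(pfs = rexp(n, cRatePfs), os = rexp(n, cRatePfs * 0.6))
    })
    pfsTime <- pmin(surv$pfs, cens$pfs)
    pfsEvent <- as.integer(surv$pfs <= cens$pfs)
    osTime <- pmin(surv$os, cens$os)
    osEvent <- as.integer(surv$os <= cens$os)
  } else {
    pfsTime <- surv$pfs; pfsEvent <- rep(1L, n)
    osTime <- surv$os; osEvent <- rep(1L, n)
  }

  covars <- .withSeed(sub[5L], {
    data.frame(
      tumor_type = sample(c("cutaneous", "non-cutaneous"), n, TRUE,
                          prob = c(0.8, 0.2)),
      mutation_type = sample(c("BRAF", "NRAS", "WT"), n, TRUE,
                             prob = c(0.4, 0.2, 0.4)),
      stage = sample(c("III", "IV"), n, TRUE, prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE)
  })

  clinical <- data.frame(sample_id = sampleIds, response = response,
                         os_time = osTime, os_event = osEvent,
                         pfs_time = pfsTime, pfs_event = pfsEvent,
                         covars, stringsAsFactors = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = 2 ^ logE),
    colData = S4Vectors::DataFrame(clinical, row.names = sampleIds),
    metadata = list(
      truth = list(informativePairs = config$informativePairs,
                   z = setNames(z, sampleIds),
                   responderIds = sampleIds[respIdx]),
      config = config))
}

#' Expression matrix of a simulated cohort
#' @param cohort SummarizedExperiment from [simulateCohort()].
#' @return genes-by-samples TPM matrix.
#' @export
cohortExpression <- function(cohort) {
  SummarizedExperiment::assay(cohort, "tpm")
}

#' Clinical table of a simulated cohort
#' @param cohort SummarizedExperiment from [simulateCohort()].
#' @return data.frame with sample_id, response, survival columns and
#'   covariates.
#' @export
cohortClinical <- function(cohort) {
  df <- as.data.frame(SummarizedExperiment::colData(cohort))
  rownames(df) <- NULL
  df
}

#' Ground truth of a simulated cohort
#' @param cohort SummarizedExperiment from [simulateCohort()].
#' @return list: informativePairs, z (latent signal), responderIds.
#' @export
cohortTruth <- function(cohort) {
  S4Vectors::metadata(cohort)$truth
}
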