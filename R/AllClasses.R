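#' @import methods
#' @importFrom stats plogis pchisq pnorm rnorm rexp rbinom runif sd var
#'   quantile setNames coef predict as.formula median complete.cases
NULL

#' Catalog of ligand-receptor pairs expanded to gene sets
#'
#' Holds ligand-receptor pairs as parallel gene lists. Receptor (or ligand)
#' complexes are stored as character vectors of subunit gene symbols, e.g.
#' the integrin complex \code{ITGA2B/ITGB3} becomes \code{c("ITGA2B",
#' "ITGB3")}. The gene set of a pair is the deduplicated union of ligand and
#' receptor members; self-pairs (identical ligand and receptor, such as
#' \code{LY9-LY9}) legitimately collapse to a single-gene set.
#'
#' @slot pairId character vector of unique pair identifiers
#'   ("LIGAND-RECEPTOR", complexes "/"-delimited).
#' @slot ligandGenes list of character vectors, ligand subunit genes per pair.
#' @slot receptorGenes list of character vectors, receptor subunit genes per
#'   pair.
#'
#' @seealso [readLRPairs()], [geneSets()], [makeDefaultCatalog()]
#' @export
setClass("LRPairCatalog",
  representation(
    pairId = "character",
    ligandGenes = "list",
    receptorGenes = "list"
  )
)

setValidity("LRPairCatalog", function(object) {
  n <- length(object@pairId)
  msg <- character()
  if (length(object@ligandGenes) != n || length(object@receptorGenes) != n)
    msg <- c(msg, "pairId, ligandGenes and receptorGenes must be parallel")
  if (anyDuplicated(object@pairId))
    msg <- c(msg, "duplicate pair identifiers")
  if (n > 0) {
    for (i in seq_len(n)) {
      lg <- object@ligandGenes[[i]]
      rg <- object@receptorGenes[[i]]
      if (!is.character(lg) || !is.character(rg) ||
          length(lg) < 1L || length(rg) < 1L ||
          any(!nzchar(c(lg, rg)))) {
        msg <- c(msg, sprintf("pair '%s': empty ligand or receptor gene",
                              object@pairId[i]))
        next
      }
      gs <- unique(c(lg, rg))
      selfPair <- setequal(lg, rg)
      if (length(gs) < 2L && !selfPair)
        msg <- c(msg, sprintf(
          "pair '%s': gene set has fewer than 2 members and is not a self-pair",
          object@pairId[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pairs-by-samples matrix of single-sample enrichment scores
#'
#' @slot scores numeric matrix, pairs in rows, samples in columns.
#' @slot exponent numeric, the rank-weighting exponent used.
#' @slot normalization character, "raw" or "range" (scores divided by the
#'   global max - min of the raw matrix).
#' @slot droppedPairs character, pairs with no measured member genes that
#'   were dropped during scoring.
#'
#' @seealso [scorePairs()]
#' @export
setClass("PairScoreMatrix",
  representation(
    scores = "matrix",
    exponent = "numeric",
    normalization = "character",
    droppedPairs = "character"
  )
)

setValidity("PairScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (!is.numeric(s)) msg <- c(msg, "scores must be numeric")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must carry pair (row) and sample (column) names")
  if (!object@normalization %in% c("raw", "range"))
    msg <- c(msg, "normalization must be 'raw' or 'range'")
  if (length(object@exponent) != 1L || object@exponent < 0)
    msg <- c(msg, "exponent must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Fitted cost-sensitive elastic-net logistic regression
#'
#' Result of [fitEnlr()]: a penalized logistic model of response (R vs NR)
#' on pair enrichment scores, with a prior-probability offset encoding the
#' empirical class frequencies against the decision threshold tau, and the
#' regularization strength selected by stratified cross-validation
#' maximizing held-out AUC.
#'
#' @slot intercept numeric, unpenalized intercept (original score scale).
#' @slot coefficients named numeric, one coefficient per retained feature
#'   (original score scale; zeros for unselected pairs).
#' @slot offset numeric, the constant prior-probability offset used during
#'   fitting.
#' @slot lambdaOpt numeric, regularization strength maximizing mean CV AUC.
#' @slot alpha numeric, elastic-net mixing parameter.
#' @slot tau numeric, predefined classification threshold behind the offset.
#' @slot cvCurve data.frame with columns lambda, aucMean, aucSD over the
#'   full grid.
#' @slot classCounts named integer, training samples per class (NR, R).
#' @slot standardize logical, whether features were standardized internally.
#' @slot seed integer, seed used for fold assignment.
#' @slot path the full-data glmnet regularization path (for diagnostics).
#'
#' @export
setClass("EnlrFit",
  representation(
    intercept = "numeric",
    coefficients = "numeric",
    offset = "numeric",
    lambdaOpt = "numeric",
    alpha = "numeric",
    tau = "numeric",
    cvCurve = "data.frame",
    classCounts = "integer",
    standardize = "logical",
    seed = "integer",
    path = "ANY"
  )
)

setValidity("EnlrFit", function(object) {
  msg <- character()
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named by pair")
  if (!all(c("lambda", "aucMean", "aucSD") %in% names(object@cvCurve)))
    msg <- c(msg, "cvCurve must have columns lambda, aucMean, aucSD")
  if (length(object@lambdaOpt) != 1L || object@lambdaOpt <= 0)
    msg <- c(msg, "lambdaOpt must be a single positive number")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@tau <= 0 || object@tau >= 1)
    msg <- c(msg, "tau must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Frozen ligand-receptor pair signature
#'
#' Portable artifact produced by [buildSignature()]: the pairs with nonzero
#' effect sizes, their gene sets (so validation cohorts can be rescored
#' without the full catalog), the logistic model's intercept and offset, the
#' scoring settings, and the decision thresholds (Youden probability
#' threshold and the mean-odds-ratio high/low cutoff from the training
#' cohort).
#'
#' @slot selectedPairs character, pairs with nonzero coefficients.
#' @slot effectSizes named numeric, coefficients of the selected pairs
#'   (original score scale).
#' @slot geneSets named list, member genes per selected pair.
#' @slot intercept numeric.
#' @slot offset numeric, prior-probability offset used during fitting.
#' @slot lambdaOpt,alpha,tau numeric tuning parameters of the fit.
#' @slot exponent,normalization scoring settings the signature expects.
#' @slot youdenThreshold numeric, probability threshold for the R call.
#' @slot orCutoff numeric, mean per-sample odds ratio in the training cohort.
#' @slot provenance list: seed, package version, training sample counts,
#'   catalog pair ids.
#'
#' @export
setClass("LRSignature",
  representation(
    selectedPairs = "character",
    effectSizes = "numeric",
    geneSets = "list",
    intercept = "numeric",
    offset = "numeric",
    lambdaOpt = "numeric",
    alpha = "numeric",
    tau = "numeric",
    exponent = "numeric",
    normalization = "character",
    youdenThreshold = "numeric",
    orCutoff = "numeric",
    provenance = "list"
  )
)

setValidity("LRSignature", function(object) {
  msg <- character()
  k <- length(object@selectedPairs)
  if (length(object@effectSizes) != k ||
      !identical(names(object@effectSizes), object@selectedPairs))
    msg <- c(msg, "effectSizes must be keyed identically to selectedPairs")
  if (!identical(sort(as.character(names(object@geneSets))),
                 sort(object@selectedPairs)))
    msg <- c(msg, "geneSets must cover exactly the selected pairs")
  if (k > 0 && sum(abs(object@effectSizes)) <= 0)
    msg <- c(msg, "weight normalizer sum(|w|) must be positive")
  if (length(object@youdenThreshold) != 1L ||
      !is.finite(object@youdenThreshold))
    msg <- c(msg, "youdenThreshold must be a single finite number")
  if (length(msg)) msg else TRUE
})
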