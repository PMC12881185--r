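#' @rdname LRPairCatalog-class
#' @param object an object.
#' @export
setGeneric("pairIds", function(object) standardGeneric("pairIds"))

#' @rdname LRPairCatalog-class
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname PairScoreMatrix-class
#' @param object an object.
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname EnlrFit-class
#' @param object an object.
#' @export
setGeneric("selectedPairs", function(object) standardGeneric("selectedPairs"))

#' @rdname EnlrFit-class
#' @export
setGeneric("effectSizes", function(object) standardGeneric("effectSizes"))

#' Accessors for LRPairCatalog
#'
#' @param object,x an \code{LRPairCatalog}.
#' @name LRPairCatalog-accessors
NULL

#' @rdname LRPairCatalog-class
#' @export
setMethod("pairIds", "LRPairCatalog", function(object) object@pairId)

#' @rdname LRPairCatalog-class
#' @export
setMethod("geneSets", "LRPairCatalog", function(object) {
  out <- mapply(function(l, r) unique(c(l, r)),
                object@ligandGenes, object@receptorGenes,
                SIMPLIFY = FALSE)
  names(out) <- object@pairId
  out
})

#' @rdname LRPairCatalog-class
#' @param x an \code{LRPairCatalog}.
#' @export
setMethod("length", "LRPairCatalog", function(x) length(x@pairId))

#' @rdname LRPairCatalog-class
#' @param i index or pair-id subset.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LRPairCatalog", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, x@pairId)
    if (length(miss))
      stop("unknown pair id(s): ", paste(miss, collapse = ", "))
    i <- match(i, x@pairId)
  }
  new("LRPairCatalog",
      pairId = x@pairId[i],
      ligandGenes = x@ligandGenes[i],
      receptorGenes = x@receptorGenes[i])
})

setMethod("show", "LRPairCatalog", function(object) {
  cat("LRPairCatalog with", length(object), "ligand-receptor pairs\n")
  gs <- geneSets(object)
  cat("  genes covered:", length(unique(unlist(gs))), "\n")
  nshow <- min(5L, length(object))
  if (nshow > 0)
    cat("  pairs:", paste(utils::head(object@pairId, nshow), collapse = ", "),
        if (length(object) > nshow) "..." else "", "\n")
})

#' @rdname PairScoreMatrix-class
#' @export
setMethod("scores", "PairScoreMatrix", function(object) object@scores)

#' @rdname PairScoreMatrix-class
#' @param x a \code{PairScoreMatrix}.
#' @export
setMethod("pairIds", "PairScoreMatrix", function(object) {
  rownames(object@scores)
})

#' @rdname PairScoreMatrix-class
#' @export
setMethod("dim", "PairScoreMatrix", function(x) dim(x@scores))

setMethod("show", "PairScoreMatrix", function(object) {
  cat("PairScoreMatrix:", nrow(object@scores), "pairs x",
      ncol(object@scores), "samples\n")
  cat("  exponent:", object@exponent,
      " normalization:", object@normalization, "\n")
  if (length(object@droppedPairs))
    cat("  dropped pairs (no measured genes):",
        length(object@droppedPairs), "\n")
})

#' @rdname EnlrFit-class
#' @export
setMethod("selectedPairs", "EnlrFit", function(object) {
  names(object@coefficients)[object@coefficients != 0]
})

#' @rdname EnlrFit-class
#' @export
setMethod("effectSizes", "EnlrFit", function(object) {
  object@coefficients[object@coefficients != 0]
})

setMethod("show", "EnlrFit", function(object) {
  cat("EnlrFit: cost-sensitive elastic-net logistic regression\n")
  cat(sprintf("  %d features, %d selected at lambda = %.4g (alpha = %.2g)\n",
              length(object@coefficients), length(selectedPairs(object)),
              object@lambdaOpt, object@alpha))
  cat(sprintf("  classes: R = %d, NR = %d; offset = %.4f (tau = %.4g)\n",
              object@classCounts[["R"]], object@classCounts[["NR"]],
              object@offset, object@tau))
  best <- max(object@cvCurve$aucMean, na.rm = TRUE)
  cat(sprintf("  best mean CV AUC: %.3f\n", best))
})

#' @rdname LRSignature-class
#' @export
setMethod("selectedPairs", "LRSignature", function(object) {
  object@selectedPairs
})

#' @rdname LRSignature-class
#' @export
setMethod("effectSizes", "LRSignature", function(object) object@effectSizes)

#' @rdname LRSignature-class
#' @export
setMethod("geneSets", "LRSignature", function(object) object@geneSets)

setMethod("show", "LRSignature", function(object) {
  cat("LRSignature:", length(object@selectedPairs), "selected pairs\n")
  if (length(object@selectedPairs)) {
    w <- sort(object@effectSizes, decreasing = TRUE)
    for (p in names(w)) cat(sprintf("    %-28s %+.4f\n", p, w[[p]]))
  }
  cat(sprintf("  Youden threshold: %.4f  mean-OR cutoff: %.4g\n",
              object@youdenThreshold, object@orCutoff))
  cat(sprintf("  lambda = %.4g, alpha = %.2g, tau = %.4g, offset = %.4f\n",
              object@lambdaOpt, object@alpha, object@tau, object@offset))
})
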