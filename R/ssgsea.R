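# Single-sample GSEA: per-sample weighted-ECDF running-sum enrichment of a
# gene set, the score underlying each ligand-receptor pair.

#' Rank genes within one sample
#'
#' Ranks are 1..N with N assigned to the highest expression. Ties are broken
#' by stable input order: among tied values the earlier gene receives the
#' higher rank. Deterministic across runs; any strictly monotone transform
#' of the expression vector yields identical ranks.
#'
#' @param x numeric expression vector for one sample (length >= 2).
#' @return integer rank vector, names preserved.
#' @export
rankGenes <- function(x) {
  if (length(x) < 2L) stop("need at least 2 genes to rank")
  r <- length(x) + 1L - rank(-as.numeric(x), ties.method = "first")
  names(r) <- names(x)
  as.integer(r)
}

#' Single-sample enrichment score of one gene set
#'
#' Walks the ranked list from highest to lowest expression and accumulates
#' the difference between the weighted in-set ECDF and the uniform
#' out-of-set ECDF:
#' \deqn{ES = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]}
#' where \eqn{P_{in}(i)} is the rank^w-weighted fraction of set members at
#' or above position i and \eqn{P_{out}(i)} the plain fraction of
#' non-members. Well-defined for single-gene sets (self-pairs).
#'
#' @param ranks integer rank vector from [rankGenes()] (1..N, N = highest).
#' @param geneSet integer indices into \code{ranks}, or gene names matched
#'   against \code{names(ranks)}.
#' @param wExp rank-weighting exponent, default 0.25.
#' @return a single numeric enrichment score.
#' @export
ssgseaScore <- function(ranks, geneSet, wExp = 0.25) {
  N <- length(ranks)
  if (is.character(geneSet)) {
    idx <- match(geneSet, names(ranks))
    if (anyNA(idx))
      stop("gene(s) not in ranked list: ",
           paste(geneSet[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(geneSet)
  idx <- unique(idx)
  m <- length(idx)
  if (m == 0L) stop("empty gene set")
  if (m >= N) stop("gene set covers all genes; out-of-set ECDF undefined")
  r <- as.numeric(ranks)
  # position in the high-to-low walk: rank N walks first
  pos <- N + 1L - r
  w <- r[idx]^wExp
  # sum over positions of the running ECDFs has the closed form
  # sum_i P_in(i) = sum_{g in G} w_g (N - pos_g + 1) / W, and analogously
  # for P_out with unit weights; avoids materializing the N-step walk.
  tailLen <- N + 1 - pos
  sumPin <- sum(w * tailLen[idx]) / sum(w)
  sumPoutAll <- N * (N + 1) / 2   # sum of tail lengths over all genes
  sumPout <- (sumPoutAll - sum(tailLen[idx])) / (N - m)
  sumPin - sumPout
}

#' Score every ligand-receptor pair in every sample
#'
#' Computes the per-sample enrichment score of each pair's gene set. Pairs
#' whose member genes are entirely absent from the matrix are dropped with
#' a warning; pairs with some members missing are scored on the measured
#' subset (logged via message), to tolerate platform differences between
#' cohorts. Scoring is rank-based, so monotone per-sample transforms of the
#' expression (e.g. log2(TPM+1)) leave the result unchanged.
#'
#' @param expr genes-by-samples numeric matrix (see [readExpression()]).
#' @param pairs an [LRPairCatalog-class], or a named list of gene-symbol
#'   vectors (one gene set per pair).
#' @param wExp rank-weighting exponent, default 0.25.
#' @param normalize "raw", or "range" to divide the whole matrix by the
#'   global (max - min) of the raw scores so that the matrix spans 1.
#' @return a [PairScoreMatrix-class].
#' @export
scorePairs <- function(expr, pairs, wExp = 0.25,
                       normalize = c("raw", "range")) {
  normalize <- match.arg(normalize)
  validateExpression(expr)
  gs <- if (is(pairs, "LRPairCatalog")) geneSets(pairs) else pairs
  if (is.null(names(gs)) || any(!nzchar(names(gs))))
    stop("pair gene sets must be named")
  genes <- rownames(expr)
  measured <- lapply(gs, function(g) match(intersect(g, genes), genes))
  nMember <- lengths(measured)
  dropped <- names(gs)[nMember == 0L]
  if (length(dropped) == length(gs))
    stop("no pair has any measured member gene")
  if (length(dropped))
    warning("dropping ", length(dropped),
            " pair(s) with no measured member genes: ",
            paste(dropped, collapse = ", "))
  partial <- names(gs)[nMember > 0L & nMember < lengths(gs)]
  if (length(partial))
    message(length(partial),
            " pair(s) scored on a measured subset of their genes")
  keep <- names(gs)[nMember > 0L]
  measured <- measured[keep]
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(expr),
                dimnames = list(keep, colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    rj <- rankGenes(expr[, j])
    for (p in keep) out[p, j] <- ssgseaScore(rj, measured[[p]], wExp = wExp)
  }
  if (normalize == "range") {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
    else warning("constant raw score matrix; range normalization skipped")
  }
  new("PairScoreMatrix", scores = out, exponent = wExp,
      normalization = normalize, droppedPairs = dropped)
}
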