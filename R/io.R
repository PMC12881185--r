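# Tabular input/output: TPM expression, clinical tables, LR-pair catalogs.
# All files are UTF-8 TSV. Gene symbols are case-sensitive and never remapped.

#' Read a genes-by-samples TPM expression matrix
#'
#' Expects a TSV whose first column ("gene") holds gene symbols and whose
#' remaining columns are samples. Values must be non-negative TPM. Duplicate
#' gene rows are collapsed by the per-sample maximum; duplicate sample
#' columns are an error. Missing cells are rejected unless
#' \code{zeroFillMissing = TRUE}, in which case they are set to 0 with a
#' warning.
#'
#' @param path path to the TSV file.
#' @param transform "none" or "log2p1" (apply log2(TPM + 1) after
#'   validation; recorded in the "transform" attribute). Enrichment scoring
#'   is rank-based, so the transform does not change pair scores.
#' @param zeroFillMissing replace missing cells by 0 instead of failing.
#' @return numeric matrix (genes x samples) with attribute "transform".
#' @export
readExpression <- function(path, transform = c("none", "log2p1"),
                           zeroFillMissing = FALSE) {
  transform <- match.arg(transform)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 3L)
    stop("expression file must have a gene column and at least 2 samples")
  genes <- as.character(raw[[1L]])
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample column(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  body <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(genes, sampleIds))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1L]], genes[bad[1L]], sampleIds[j]))
      col <- num
    }
    mat[, j] <- as.numeric(col)
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    if (!zeroFillMissing)
      stop(sprintf("missing value at gene '%s', sample '%s' (use zeroFillMissing = TRUE to zero-fill)",
                   genes[idx[1L]], sampleIds[idx[2L]]))
    warning(sum(is.na(mat)), " missing value(s) zero-filled")
    mat[is.na(mat)] <- 0
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value %g at gene '%s', sample '%s'",
                 mat[idx[1L], idx[2L]], genes[idx[1L]], sampleIds[idx[2L]]))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup),
            " duplicated gene symbol(s) by per-sample maximum")
    keep <- unique(genes)
    collapsed <- matrix(NA_real_, length(keep), ncol(mat),
                        dimnames = list(keep, sampleIds))
    for (g in keep) {
      rows <- mat[genes == g, , drop = FALSE]
      collapsed[g, ] <- apply(rows, 2L, max)
    }
    mat <- collapsed
  }
  validateExpression(mat)
  if (transform == "log2p1") mat <- log2(mat + 1)
  attr(mat, "transform") <- transform
  mat
}

#' Validate an expression matrix in memory
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validateExpression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression must carry gene rownames and sample colnames")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("expression needs at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (anyNA(mat)) stop("expression contains missing values")
  if (any(mat < 0)) stop("expression contains negative values")
  invisible(mat)
}

#' Write an expression matrix as TSV
#'
#' @param mat genes-by-samples numeric matrix.
#' @param path output path.
#' @export
writeExpression <- function(mat, path) {
  validateExpression(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive the response label from RECIST-style fields
#'
#' A sample is a responder (R) on complete/partial response or
#' progression-free survival beyond the cutoff; a non-responder (NR) on
#' progressive disease with PFS under the cutoff; otherwise "unknown"
#' (excluded from model fitting but still scored).
#'
#' @param bestResponse character: CR, PR, SD or PD (NA allowed).
#' @param pfsTime numeric PFS in days (NA allowed).
#' @param pfsEvent optional 0/1 progression flag (unused by the rule; kept
#'   for interface completeness).
#' @param cutoffDays positive PFS cutoff, default 180.
#' @return character vector over {"R", "NR", "unknown"}.
#' @export
deriveResponse <- function(bestResponse, pfsTime, pfsEvent = NULL,
                           cutoffDays = 180) {
  stopifnot(cutoffDays > 0)
  n <- max(length(bestResponse), length(pfsTime))
  bestResponse <- rep_len(as.character(bestResponse), n)
  pfsTime <- rep_len(as.numeric(pfsTime), n)
  out <- rep("unknown", n)
  isR <- (!is.na(bestResponse) & bestResponse %in% c("CR", "PR")) |
         (!is.na(pfsTime) & pfsTime > cutoffDays)
  isNR <- !isR &
          !is.na(pfsTime) & pfsTime < cutoffDays &
          !is.na(bestResponse) & bestResponse == "PD"
  out[isR] <- "R"
  out[isNR] <- "NR"
  out
}

#' Read a per-sample clinical table
#'
#' Requires a \code{sample_id} column and either a precomputed
#' \code{response} column (values R/NR/unknown) or raw fields
#' (\code{best_response} in CR/PR/SD/PD plus \code{pfs_time}) from which the
#' response is derived via [deriveResponse()]. Optional columns:
#' \code{os_time}, \code{os_event}, \code{pfs_time}, \code{pfs_event} and
#' arbitrary covariates.
#'
#' @param path path to the TSV file.
#' @param pfsCutoffDays PFS cutoff for the derived response, default 180.
#' @return data.frame with one row per sample and a \code{response} column.
#' @export
readClinical <- function(path, pfsCutoffDays = 180) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) stop("clinical table lacks 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyNA(df$sample_id) || any(!nzchar(df$sample_id)))
    stop("missing sample_id")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (tc in c("os_time", "pfs_time")) {
    if (tc %in% names(df)) {
      df[[tc]] <- as.numeric(df[[tc]])
      if (any(df[[tc]] < 0, na.rm = TRUE))
        stop("negative time in column '", tc, "'")
    }
  }
  for (ec in c("os_event", "pfs_event")) {
    if (ec %in% names(df)) {
      df[[ec]] <- as.numeric(df[[ec]])
      if (!all(df[[ec]] %in% c(0, 1) | is.na(df[[ec]])))
        stop("event flags in '", ec, "' must be 0/1")
    }
  }
  if (!"response" %in% names(df)) {
    if (!"best_response" %in% names(df))
      stop("clinical table needs 'response' or 'best_response'")
    df$response <- deriveResponse(df$best_response,
                                  if ("pfs_time" %in% names(df))
                                    df$pfs_time else NA_real_,
                                  cutoffDays = pfsCutoffDays)
  } else {
    df$response <- as.character(df$response)
    bad <- setdiff(unique(df$response), c("R", "NR", "unknown", NA))
    if (length(bad))
      stop("invalid response value(s): ", paste(bad, collapse = ", "))
    df$response[is.na(df$response)] <- "unknown"
  }
  df
}

#' Write a clinical table as TSV
#' @param clinical data.frame with a sample_id column.
#' @param path output path.
#' @export
writeClinical <- function(clinical, path) {
  stopifnot("sample_id" %in% names(clinical))
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.splitComplex <- function(x, what, pairLabel) {
  if (is.na(x) || !nzchar(trimws(x)))
    stop("empty ", what, " field in pair ", pairLabel)
  parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 0L || any(!nzchar(trimws(parts))) ||
      grepl("^/|/$|//", x))
    stop("malformed complex '", x, "' in ", what, " of pair ", pairLabel)
  trimws(parts)
}

#' Build a ligand-receptor pair catalog from ligand/receptor strings
#'
#' @param ligand,receptor character vectors; complexes "/"-delimited.
#' @return an [LRPairCatalog-class].
#' @export
makeLRPairCatalog <- function(ligand, receptor) {
  stopifnot(length(ligand) == length(receptor))
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  pairId <- paste(ligand, receptor, sep = "-")
  lg <- vector("list", length(ligand))
  rg <- vector("list", length(ligand))
  for (i in seq_along(ligand)) {
    lg[[i]] <- .splitComplex(ligand[i], "ligand", pairId[i])
    rg[[i]] <- .splitComplex(receptor[i], "receptor", pairId[i])
  }
  new("LRPairCatalog", pairId = pairId, ligandGenes = lg, receptorGenes = rg)
}

#' Read a ligand-receptor pair list
#'
#' TSV with columns \code{ligand} and \code{receptor}; multi-subunit
#' complexes are "/"-delimited (e.g. receptor \code{ITGA2B/ITGB3}).
#'
#' @param path path to the TSV file.
#' @return an [LRPairCatalog-class].
#' @export
readLRPairs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("LR pair table needs columns 'ligand' and 'receptor'")
  makeLRPairCatalog(df$ligand, df$receptor)
}

#' Write a ligand-receptor pair catalog as TSV
#' @param catalog an [LRPairCatalog-class].
#' @param path output path.
#' @export
writeLRPairs <- function(catalog, path) {
  df <- data.frame(
    ligand = vapply(catalog@ligandGenes, paste, "", collapse = "/"),
    receptor = vapply(catalog@receptorGenes, paste, "", collapse = "/"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
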