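# Serialization of the fitted signature as schema-versioned JSON.

.MODEL_SCHEMA <- "lrpsig-model"
.MODEL_SCHEMA_VERSION <- 1L

#' Write a fitted signature to JSON
#'
#' The artifact is schema-versioned and round-trips losslessly (doubles are
#' written at full precision). Only pairs with nonzero coefficients are
#' stored, together with their gene sets, so the model is portable to
#' cohorts profiled on different platforms.
#'
#' @param signature an [LRSignature-class].
#' @param path output path (.json).
#' @export
writeModel <- function(signature, path) {
  stopifnot(is(signature, "LRSignature"))
  validObject(signature)
  payload <- list(
    schema = .MODEL_SCHEMA,
    schemaVersion = .MODEL_SCHEMA_VERSION,
    signature = list(
      selectedPairs = signature@selectedPairs,
      effectSizes = as.list(signature@effectSizes),
      geneSets = signature@geneSets,
      intercept = signature@intercept,
      offset = signature@offset,
      lambdaOpt = signature@lambdaOpt,
      alpha = signature@alpha,
      tau = signature@tau,
      exponent = signature@exponent,
      normalization = signature@normalization,
      youdenThreshold = signature@youdenThreshold,
      orCutoff = signature@orCutoff
    ),
    provenance = signature@provenance
  )
  # I(17) significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a fitted signature from JSON
#'
#' @param path path written by [writeModel()].
#' @return an [LRSignature-class].
#' @export
readModel <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  if (!identical(payload$schema, .MODEL_SCHEMA))
    stop("not a ", .MODEL_SCHEMA, " artifact: ", path)
  if (!identical(as.integer(payload$schemaVersion), .MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version '", payload$schemaVersion,
         "' (this package reads version ", .MODEL_SCHEMA_VERSION, ")")
  s <- payload$signature
  selected <- as.character(unlist(s$selectedPairs))
  eff <- vapply(s$effectSizes, as.numeric, numeric(1))
  eff <- setNames(as.numeric(eff), names(s$effectSizes))[selected]
  if (length(selected) == 0L) eff <- setNames(numeric(0), character(0))
  gs <- lapply(s$geneSets, function(g) as.character(unlist(g)))
  new("LRSignature",
      selectedPairs = selected,
      effectSizes = eff,
      geneSets = gs[selected],
      intercept = as.numeric(s$intercept),
      offset = as.numeric(s$offset),
      lambdaOpt = as.numeric(s$lambdaOpt),
      alpha = as.numeric(s$alpha),
      tau = as.numeric(s$tau),
      exponent = as.numeric(s$exponent),
      normalization = as.character(s$normalization),
      youdenThreshold = as.numeric(s$youdenThreshold),
      orCutoff = as.numeric(s$orCutoff),
      provenance = payload$provenance)
}
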