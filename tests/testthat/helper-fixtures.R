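# Small in-code fixtures shared across test files.

writeTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyExpression <- function() {
  m <- matrix(c(5, 1, 3,
                2, 8, 1,
                0, 4, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2", "s3")))
  m
}

toyCatalog <- function() {
  makeLRPairCatalog(c("GA", "GB"), c("GB", "GC"))
}

# Strong-signal cohort small enough for repeated fitting in tests.
quickCohort <- function(seed, n = 80, delta = 2, nPairs = 20,
                        nGenes = 200, frac = 0.4, censorRate = 0.2,
                        hazardCoef = 1) {
  catalog <- makeDefaultCatalog(nPairs, seed = 1)
  cfg <- simulationConfig(nSamples = n, responderFraction = frac,
                          nGenes = nGenes, catalog = catalog,
                          informativePairs = pairIds(catalog)[1:5],
                          delta = delta, hazardCoef = hazardCoef,
                          censorRate = censorRate, seed = seed)
  simulateCohort(cfg)
}
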