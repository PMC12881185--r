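# Internal helpers.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive component sub-seeds from a master seed (fixed offsets, kept below
# 2^31 so they remain valid R integers).
.subSeeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

# Significance wording used throughout: < 0.05 significant, (0.05, 0.1]
# reported as a trend.
#' Label a p-value following the reporting convention
#' @param p numeric p-value(s).
#' @return character: "significant", "trend" or "ns".
#' @export
pValueLabel <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p <= 0.1, "trend", "ns"))
}
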