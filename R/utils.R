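## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library code never perturbs user sessions.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic sub-seed derivation; keeps results below 2^31 - 1.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

## Upper-triangle node pairs in lexicographic (i, j) order, i < j.
## This ordering is the deterministic tie-break used everywhere edges are
## ranked, so binarization is reproducible even with tied correlations.
nodePairs <- function(n) {
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
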