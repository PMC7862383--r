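`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a deterministic RNG state derived from `seed`,
# restoring the caller's RNG state afterwards. All stochastic steps in the
# package flow through this helper so a single config seed reproduces a run
# bit-for-bit.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
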