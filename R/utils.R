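# Run expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL/NA leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# (1 - 1/(2Ne))^t, robust to Ne = Inf
driftRetention <- function(Ne, t) {
  if (is.infinite(Ne)) return(1)
  (1 - 1 / (2 * Ne))^t
}
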