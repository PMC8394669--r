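#' Evaluate code with a locally-set RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so surrounding code is unaffected. A `NULL` seed
#' evaluates the code against the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# nearest-rank lower quantile: largest value v in the sorted sample such that
# at least `prob` of the mass is <= v is NOT what we want for the band count;
# we take the smallest value whose empirical CDF reaches `prob`.
nearest_rank_quantile <- function(x, prob) {
  stopifnot(length(x) > 0, prob > 0, prob <= 1)
  xs <- sort(x)
  xs[ceiling(prob * length(xs))]
}
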