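# Seed handling: every exported stochastic operation takes one integer seed
# and restores the caller's RNG state on exit, so a single master seed
# reproduces an entire pipeline run without clobbering the session RNG.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stream of stage seeds from one master seed
#'
#' All stages of a pipeline run draw their seeds from this stream, so a
#' single integer reproduces the whole run. Derived seeds stay in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n, replace = FALSE))
}
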