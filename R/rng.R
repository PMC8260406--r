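# Seeded-randomness helpers. All stochastic functions in the package take an
# explicit `seed` argument and route it through these, so no call mutates the
# caller's .Random.seed and identical seeds give byte-identical results.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the random-number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards, so package functions never disturb
#' global reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a child seed from a parent seed and a stream index
#'
#' Deterministic integer mixing (splitmix-style multiplicative hash reduced
#' mod 2^31 - 1) so that independent random streams (one per video, per
#' epoch, ...) can be derived from a single user-facing seed.
#'
#' @param seed Parent integer seed.
#' @param ... One or more integer stream indices.
#' @return A single integer in [1, 2^31 - 2].
#' @keywords internal
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed) %% m
  for (k in idx) {
    # multiply-and-add in double precision; operands stay < 2^53
    s <- (s * 48271 + (as.double(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 2L) + 1L)
}
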