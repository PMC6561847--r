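#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed with max-subtraction.
#' @export
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a root seed
#'
#' Deterministic integer stream-splitting: each index in \code{...} advances a
#' multiplicative-congruential mix modulo 2^31 - 1. Used to give every
#' (model, class, trajectory, replicate) combination its own reproducible
#' random stream from a single root seed.
#'
#' @param seed integer root seed.
#' @param ... integer indices identifying the substream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (k in c(...)) {
    h <- (h * 48271 + as.double(k) + 11) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# run expr under a locally-set seed without clobbering the caller's RNG state;
# seed = NULL leaves the current stream untouched
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# capability errors signal that an exact 2^n computation was refused; callers
# are directed to the particle engine
capabilityError <- function(msg) {
  stop(errorCondition(msg, class = c("pobdsCapabilityError", "error", "condition")))
}

# default guard on materializing 2^n-sized objects
.matrixGuard <- function() getOption("scPOBDS.matrixGuard", 14L)

checkMatrixGuard <- function(n, what = "exact computation") {
  guard <- .matrixGuard()
  if (n > guard)
    capabilityError(sprintf(
      "%s would materialize 2^%d-sized structures (guard: n <= %d); use the particle engine or raise options(scPOBDS.matrixGuard=)",
      what, n, guard))
  invisible(TRUE)
}
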