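## Likelihood engines: a common interface over the exact Boolean Kalman
## filter and the particle approximations, so classifiers can be
## parameterized by either.

#' Likelihood engines
#'
#' An engine computes trajectory log-likelihoods under a
#' \linkS4class{PobdsModel}. \code{exactEngine} uses the matrix Boolean
#' Kalman filter (Gaussian family, n within the matrix guard);
#' \code{apfEngine} uses the auxiliary-particle-filter approximation with
#' \code{N} particles; \code{sirEngine} the plain bootstrap filter. Particle
#' engines cache one steady-state draw pool per model (seeded from
#' \code{poolSeed}) for initialization on networks beyond the matrix guard.
#'
#' @param N number of particles.
#' @param poolSize number of cached steady-state draws per model.
#' @param poolSeed seed governing the cached pools (kept separate from
#'   per-call seeds so pools do not depend on call order).
#' @param resampling APF ancestor sampling scheme, "multinomial" (default)
#'   or "systematic".
#' @return an engine object for use with \code{\link{engineLogLik}} and the
#'   classifiers.
#' @export
exactEngine <- function() {
  structure(list(name = "exact"), class = "PobdsEngine")
}

#' @rdname exactEngine
#' @export
apfEngine <- function(N = 1000L, poolSize = 10000L, poolSeed = 1L,
                      resampling = c("multinomial", "systematic")) {
  structure(list(name = "apf", N = as.integer(N),
                 poolSize = as.integer(poolSize),
                 poolSeed = as.integer(poolSeed),
                 resampling = match.arg(resampling),
                 cache = new.env(parent = emptyenv())),
            class = "PobdsEngine")
}

#' @rdname exactEngine
#' @export
sirEngine <- function(N = 1000L, poolSize = 10000L, poolSeed = 1L) {
  e <- apfEngine(N, poolSize, poolSeed)
  e$name <- "sir"
  e
}

# steady-state pool for particle initialization; NULL when the exact
# stationary vector is materializable (categorical draws are used instead)
.enginePool <- function(engine, model) {
  if (nGenes(model) <= .matrixGuard()) return(NULL)
  key <- paste(model@modelId, model@p, model@sigma, model@noiseFamily,
               sum(model@lambda), sum(model@delta), sep = "|")
  pool <- engine$cache[[key]]
  if (is.null(pool)) {
    pool <- steadyStatePool(model, nDraws = engine$poolSize,
                            seed = childSeed(engine$poolSeed, sum(utf8ToInt(key))))
    engine$cache[[key]] <- pool
  }
  pool
}

# exact batch: share the transition matrix, update-density geometry and
# steady-state prior across trajectories of one model
.exactLogLikBatch <- function(model, trajs) {
  n <- nGenes(model)
  checkMatrixGuard(n, "exact likelihood computation")
  if (model@noiseFamily != "gaussian")
    capabilityError("the exact engine supports the Gaussian observation family only")
  M <- transitionMatrix(model)
  prior <- as.numeric(steadyState(model, method = "exact"))
  S <- stateMatrix(n)
  mu <- matrix(model@lambda, 2^n, n, byrow = TRUE) +
    S * matrix(model@delta, 2^n, n, byrow = TRUE)
  const <- -0.5 * log(2 * pi * model@sigma^2) * n
  vapply(trajs, function(y) {
    belief <- prior
    ll <- 0
    for (k in seq_len(nrow(y))) {
      d <- exp(const - rowSums((matrix(y[k, ], 2^n, n, byrow = TRUE) - mu)^2) /
                 (2 * model@sigma^2))
      u <- d * as.numeric(M %*% belief)
      s <- sum(u)
      if (s <= 0 || !is.finite(s)) stop("filter underflow in exact engine")
      belief <- u / s
      ll <- ll + log(s)
    }
    ll
  }, numeric(1))
}

#' Compute trajectory log-likelihoods through an engine
#'
#' @param engine an engine from \code{\link{exactEngine}},
#'   \code{\link{apfEngine}} or \code{\link{sirEngine}}.
#' @param model a \linkS4class{PobdsModel}.
#' @param trajs a \linkS4class{Trajectory}, matrix, or list of either.
#' @param seed integer seed for the particle engines (ignored by the exact
#'   engine, which is deterministic).
#' @return numeric vector of log-likelihoods, one per trajectory.
#' @export
engineLogLik <- function(engine, model, trajs, seed = NULL) {
  stopifnot(inherits(engine, "PobdsEngine"))
  trajs <- .trajToMatrices(trajs, nGenes(model))
  switch(engine$name,
    exact = .exactLogLikBatch(model, trajs),
    apf = apfLogLik(model, trajs, N = engine$N,
                    ssPool = .enginePool(engine, model),
                    resampling = engine$resampling, seed = seed),
    sir = sirLogLik(model, trajs, N = engine$N,
                    ssPool = .enginePool(engine, model), seed = seed),
    stop("unknown engine"))
}
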