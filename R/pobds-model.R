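## The POBDS generative model: stochastic state transitions, observation
## sampling, exact transition/update matrices and steady-state distributions.

.noiseFamilyCode <- function(family) {
  match(family, c("gaussian", "poisson", "negative_binomial")) - 1L
}

#' Construct a POBDS model
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param p Bernoulli perturbation probability, 0 < p < 0.5. Each gene's
#'   updated bit is flipped independently with probability p at every step.
#' @param lambda baseline expression; scalar recycled to all genes.
#' @param delta differential expression of the ON state; scalar recycled.
#' @param sigma observation noise sd (Gaussian / negative-binomial families).
#' @param noiseFamily "gaussian" (default), "poisson" or "negative_binomial".
#'   The negative binomial is moment-matched to the Gaussian: mean
#'   \code{lambda + delta*x}, variance \code{sigma^2} (requires
#'   \code{sigma^2 > mean}).
#' @param modelId label used in caches and reports.
#' @return a \linkS4class{PobdsModel}.
#' @examples
#' net <- parseRules("A = NOT B\nB = A")
#' m <- pobdsModel(net, p = 0.05)
#' @export
pobdsModel <- function(net, p, lambda = 10, delta = 30, sigma = 20,
                       noiseFamily = c("gaussian", "poisson", "negative_binomial"),
                       modelId = "pobds") {
  noiseFamily <- match.arg(noiseFamily)
  n <- nGenes(net)
  new("PobdsModel", net = net, p = p,
      lambda = rep_len(as.numeric(lambda), n),
      delta = rep_len(as.numeric(delta), n),
      sigma = as.numeric(sigma), noiseFamily = noiseFamily,
      modelId = as.character(modelId))
}

#' @rdname nGenes
#' @export
setMethod("nGenes", "PobdsModel", function(object) nGenes(object@net))

#' @rdname geneNames
#' @export
setMethod("geneNames", "PobdsModel", function(object) geneNames(object@net))

setMethod("show", "PobdsModel", function(object) {
  cat(sprintf("PobdsModel '%s': %d genes, p=%g, %s noise (sigma=%g)\n",
              object@modelId, nGenes(object), object@p, object@noiseFamily,
              object@sigma))
  cat(sprintf("  lambda: %s\n", paste(format(unique(object@lambda)), collapse = ", ")))
  cat(sprintf("  delta:  %s\n", paste(format(unique(object@delta)), collapse = ", ")))
  if (length(object@net@frozen))
    cat(sprintf("  frozen: %s\n",
                paste(sprintf("%s=%d", names(object@net@frozen), object@net@frozen),
                      collapse = ", ")))
})

#' One stochastic state transition
#'
#' Applies the network function and flips each resulting bit independently
#' with probability \code{p}: \code{X_k = f(X_{k-1}) XOR n_k},
#' \code{n_k ~ Bernoulli(p)^n}. Frozen genes are stuck: neither their rule
#' nor the perturbation noise can move them.
#'
#' @param model a \linkS4class{PobdsModel}.
#' @param x current 0/1 state vector.
#' @param seed optional integer seed for reproducibility.
#' @return the next 0/1 state vector.
#' @export
stepState <- function(model, x, seed = NULL) {
  fx <- evaluateState(model@net, x)
  withSeed(seed, {
    flip <- rbinom(length(fx), 1L, model@p)
    flip[match(names(model@net@frozen), geneNames(model))] <- 0L
    setNames(as.integer(bitwXor(as.integer(fx), flip)), geneNames(model))
  })
}

#' Sample one expression observation from a Boolean state
#'
#' Gaussian family: \code{y = lambda + delta*x + N(0, sigma^2)}. Poisson:
#' \code{y_j ~ Pois(lambda_j + delta_j x_j)}. Negative binomial: mean
#' \code{lambda_j + delta_j x_j}, variance \code{sigma^2}.
#'
#' @inheritParams stepState
#' @return a numeric expression vector of length n.
#' @export
sampleObservation <- function(model, x, seed = NULL) {
  x <- as.integer(x)
  mu <- model@lambda + model@delta * x
  withSeed(seed, {
    y <- switch(model@noiseFamily,
      gaussian = mu + stats::rnorm(length(mu), 0, model@sigma),
      poisson = stats::rpois(length(mu), mu),
      negative_binomial = {
        r <- mu^2 / (model@sigma^2 - mu)
        stats::rnbinom(length(mu), size = r, prob = r / (r + mu))
      })
    setNames(as.numeric(y), geneNames(model))
  })
}

#' Construct a Trajectory object
#'
#' @param y T x n observation matrix.
#' @param x optional T x n 0/1 latent state matrix.
#' @param meta metadata list.
#' @return a \linkS4class{Trajectory}.
#' @export
trajectory <- function(y, x = NULL, meta = list()) {
  y <- as.matrix(y)
  if (is.null(x)) x <- matrix(integer(), 0L, ncol(y))
  new("Trajectory", y = y, x = as.matrix(x), meta = meta)
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points x %d genes%s\n",
              nrow(object@y), ncol(object@y),
              if (nrow(object@x)) " (latent states attached)" else ""))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

# draw m time-0 states: from a supplied steady-state pool, the exact
# stationary law when materializable, or fresh Monte-Carlo chain draws
.drawInitialStates <- function(model, m, ssPool = NULL) {
  n <- nGenes(model)
  if (!is.null(ssPool)) {
    ssPool[sample.int(nrow(ssPool), m, replace = TRUE), , drop = FALSE]
  } else if (n <= .matrixGuard()) {
    pi <- steadyState(model, method = "exact")
    indexToState(sample.int(2^n, m, replace = TRUE, prob = as.numeric(pi)), n)
  } else {
    steadyStatePool(model, nDraws = m, thin = 10L)
  }
}

#' Simulate single-cell expression trajectories
#'
#' Draws the time-0 state from the model's steady-state distribution (or
#' from \code{x0} / \code{ssPool} when given), then iterates the perturbed
#' Boolean dynamics for \code{T} steps, emitting one noisy expression vector
#' per step.
#'
#' @param model a \linkS4class{PobdsModel}.
#' @param T trajectory length (number of observed time points), >= 1.
#' @param x0 optional fixed time-0 state.
#' @param nTraj number of trajectories to simulate.
#' @param ssPool optional matrix of steady-state draws (rows) to initialize
#'   from; avoids repeated burn-in for large networks.
#' @param seed optional integer seed.
#' @return a \linkS4class{Trajectory} (if \code{nTraj == 1}) or a list of
#'   them; latent states are stored in the \code{x} slot.
#' @export
simulateTrajectory <- function(model, T, x0 = NULL, nTraj = 1L, ssPool = NULL,
                               seed = NULL) {
  stopifnot(T >= 1L, nTraj >= 1L)
  n <- nGenes(model)
  cmp <- .compileNetwork(model@net)
  withSeed(seed, {
    init <- if (!is.null(x0)) {
      matrix(rep(as.integer(x0), each = nTraj), nrow = nTraj)
    } else {
      .drawInitialStates(model, nTraj, ssPool)
    }
    sim <- cpp_simulate_traj(init, as.integer(T), cmp$prog, cmp$frozenIdx,
                             cmp$frozenVal, model@p, model@lambda, model@delta,
                             model@sigma, .noiseFamilyCode(model@noiseFamily))
    out <- lapply(seq_len(nTraj), function(i) {
      rows <- ((i - 1L) * T + 1L):(i * T)
      y <- sim$y[rows, , drop = FALSE]
      x <- sim$x[rows, , drop = FALSE]
      colnames(y) <- colnames(x) <- geneNames(model)
      trajectory(y, x, meta = list(modelId = model@modelId, seed = seed))
    })
    if (nTraj == 1L) out[[1L]] else out
  })
}

#' Exact state transition matrix
#'
#' The 2^n x 2^n column-stochastic Markov matrix of the perturbed Boolean
#' chain: entry (i, j) is \code{p^d (1-p)^(n-d)} with \code{d} the Hamming
#' distance between \code{f(x^j)} and \code{x^i}. For models with frozen
#' (stuck) genes the perturbation acts on the free genes only: target states
#' that contradict a frozen value have probability zero and the exponent
#' counts free genes. Refused (with a capability error pointing at the
#' particle engine) when n exceeds the materialization guard.
#'
#' @param model a \linkS4class{PobdsModel}.
#' @return a dense 2^n x 2^n matrix whose columns sum to 1.
#' @export
transitionMatrix <- function(model) {
  n <- nGenes(model)
  checkMatrixGuard(n, "transition matrix construction")
  S <- stateMatrix(n)
  f <- evaluateState(model@net, S)
  fBits <- stateToIndex(f) - 1L
  popcount <- as.integer(rowSums(S))          # popcount[i] = bits of i-1
  idx <- 0:(2^n - 1L)
  frozenPos <- match(names(model@net@frozen), geneNames(model))
  frozenMask <- as.integer(sum(2^(frozenPos - 1L)))
  nFree <- n - length(frozenPos)
  d <- vapply(fBits, function(b) popcount[bitwXor(idx, b) + 1L],
              integer(2^n))                    # d[i, j]
  M <- matrix(model@p^d * (1 - model@p)^(nFree - d), nrow = 2^n)
  if (length(frozenPos)) {
    # rows whose frozen bits disagree with the (frozen) network output are
    # unreachable; d already counts only free genes on the remaining rows
    bad <- bitwAnd(idx, frozenMask) != bitwAnd(fBits[1], frozenMask)
    M[bad, ] <- 0
  }
  M
}

#' Observation update diagonal
#'
#' The diagonal of the Boolean Kalman filter update matrix: element i is the
#' Gaussian observation density of \code{y} given state \code{x^i},
#' \code{(2 pi sigma^2)^(-n/2) exp(-sum_j (y_j - lambda_j - delta_j x^i_j)^2
#' / (2 sigma^2))}. The exact engine is Gaussian-only.
#'
#' @param model a \linkS4class{PobdsModel} with \code{noiseFamily "gaussian"}.
#' @param y expression vector of length n.
#' @return a strictly positive vector of length 2^n.
#' @export
updateDiagonal <- function(model, y) {
  if (model@noiseFamily != "gaussian")
    capabilityError("the exact update matrix is defined for the Gaussian observation family only")
  n <- nGenes(model)
  checkMatrixGuard(n, "update diagonal construction")
  if (length(y) != n) stop("observation length must equal the number of genes")
  S <- stateMatrix(n)
  mu <- matrix(model@lambda, 2^n, n, byrow = TRUE) +
    S * matrix(model@delta, 2^n, n, byrow = TRUE)
  ll <- rowSums(dnorm(matrix(as.numeric(y), 2^n, n, byrow = TRUE),
                      mean = mu, sd = model@sigma, log = TRUE))
  exp(ll)
}

#' Steady-state distribution of the perturbed Boolean chain
#'
#' For 0 < p < 0.5 every transition probability is strictly positive, so the
#' chain is irreducible and aperiodic and has a unique stationary law. The
#' exact method runs power iteration on the explicit transition matrix; the
#' Monte-Carlo method tabulates state visits of one long simulated chain
#' after burn-in.
#'
#' @param model a \linkS4class{PobdsModel}.
#' @param method "exact" (n within the matrix guard) or "monte_carlo".
#' @param nSteps Monte-Carlo chain length after burn-in.
#' @param burnin Monte-Carlo burn-in, default 10 * n steps.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param maxIter power iteration cap; non-convergence is an error reporting
#'   the residual.
#' @param seed optional seed (Monte-Carlo method).
#' @return a \linkS4class{BeliefVector} of length 2^n.
#' @export
steadyState <- function(model, method = c("exact", "monte_carlo"),
                        nSteps = 1e5, burnin = 10L * nGenes(model),
                        tol = 1e-12, maxIter = 1e6, seed = NULL) {
  method <- match.arg(method)
  n <- nGenes(model)
  checkMatrixGuard(n, "steady-state vector materialization")
  if (method == "exact") {
    M <- transitionMatrix(model)
    v <- rep(1 / 2^n, 2^n)
    for (it in seq_len(maxIter)) {
      v2 <- as.numeric(M %*% v)
      v2 <- v2 / sum(v2)
      if (sum(abs(v2 - v)) < tol) return(new("BeliefVector", v2))
      v <- v2
    }
    stop(sprintf("power iteration did not converge within %d iterations (residual %.3e)",
                 as.integer(maxIter), sum(abs(as.numeric(M %*% v) - v))))
  } else {
    pool <- steadyStatePool(model, nDraws = nSteps, burnin = burnin, seed = seed)
    counts <- tabulate(stateToIndex(pool), nbins = 2^n)
    new("BeliefVector", counts / sum(counts))
  }
}

#' Draws from the steady-state distribution for large networks
#'
#' Runs one long realization of the perturbed Boolean chain from a uniform
#' random start and returns the visited states after burn-in (optionally
#' thinned). This is the implicit steady-state sampler used when 2^n is too
#' large to materialize: particle initialization and steady-state marginals
#' are computed from these draws.
#'
#' @param model a \linkS4class{PobdsModel}.
#' @param nDraws number of states to return.
#' @param burnin chain burn-in, default 10 * n.
#' @param thin keep every \code{thin}-th post-burn-in state.
#' @param seed optional integer seed.
#' @return an \code{nDraws} x n 0/1 matrix.
#' @export
steadyStatePool <- function(model, nDraws = 1e4, burnin = 10L * nGenes(model),
                            thin = 1L, seed = NULL) {
  cmp <- .compileNetwork(model@net)
  withSeed(seed, {
    pool <- cpp_chain_pool(cmp$prog, cmp$frozenIdx, cmp$frozenVal, model@p,
                           as.integer(nDraws * thin), as.integer(burnin))
    if (thin > 1L) pool <- pool[seq(thin, nrow(pool), by = thin), , drop = FALSE]
    colnames(pool) <- geneNames(model)
    pool
  })
}

#' Write / read trajectory CSV files
#'
#' The observation file has a header \code{time,<gene names...>} and one row
#' per time step, written at full double precision so that a write/read
#' round-trip is exact. When latent states are attached they are written to a
#' sibling file in the same layout with 0/1 entries.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output CSV path for the observations.
#' @param statesPath optional path for the latent Boolean states.
#' @return \code{writeTrajectory} returns \code{path} invisibly;
#'   \code{readTrajectory} returns a \linkS4class{Trajectory}.
#' @export
writeTrajectory <- function(traj, path, statesPath = NULL) {
  genes <- colnames(traj@y)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(traj@y)))
  hdr <- paste(c("time", genes), collapse = ",")
  rows <- vapply(seq_len(nrow(traj@y)), function(k) {
    paste(c(format(k), sprintf("%.17g", traj@y[k, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  if (!is.null(statesPath)) {
    if (!nrow(traj@x)) stop("trajectory has no latent states to write")
    rows <- vapply(seq_len(nrow(traj@x)), function(k) {
      paste(c(format(k), traj@x[k, ]), collapse = ",")
    }, character(1))
    writeLines(c(hdr, rows), statesPath)
  }
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path, statesPath = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("trajectory CSV must start with a 'time' column")
  y <- as.matrix(df[, -1, drop = FALSE])
  x <- NULL
  if (!is.null(statesPath)) {
    dfx <- read.csv(statesPath, check.names = FALSE)
    x <- matrix(as.integer(as.matrix(dfx[, -1, drop = FALSE])),
                nrow = nrow(dfx), dimnames = list(NULL, names(dfx)[-1]))
  }
  trajectory(y, x, meta = list(source = path))
}
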