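## Exact trajectory log-likelihood via the Boolean Kalman filter matrix
## recursion, plus a full-enumeration oracle used in tests.

#' One Boolean Kalman filter step
#'
#' Propagates a belief through the transition matrix, reweights by the
#' observation densities and renormalizes: with \code{u = d * (M belief)},
#' the new belief is \code{u / sum(u)} and the log-likelihood increment is
#' \code{log(sum(u))} (the scaled forward algorithm; the per-step
#' normalizers sum to the trajectory log-likelihood).
#'
#' @param belief a \linkS4class{BeliefVector} (or numeric probability vector).
#' @param M 2^n x 2^n column-stochastic transition matrix.
#' @param d strictly positive update diagonal (observation densities).
#' @return list with \code{belief} (normalized \linkS4class{BeliefVector})
#'   and \code{logIncrement}.
#' @export
bkfStep <- function(belief, M, d) {
  belief <- as.numeric(belief)
  if (length(d) != length(belief) || nrow(M) != length(belief))
    stop("belief, transition matrix and update diagonal dimensions must agree")
  if (any(d <= 0)) stop("update diagonal must be strictly positive")
  u <- d * as.numeric(M %*% belief)
  s <- sum(u)
  if (s <= 0 || !is.finite(s))
    stop("filter underflow: the one-step marginal is zero in floating point; check sigma and the observation scale")
  list(belief = new("BeliefVector", u / s), logIncrement = log(s))
}

#' Exact trajectory log-likelihood (Boolean Kalman filter)
#'
#' Runs the matrix filter recursion over a trajectory, starting from the
#' model's steady-state distribution (or a supplied prior belief), and
#' returns the sum of per-step log normalizers. Requires the Gaussian
#' observation family and n within the matrix guard; larger networks must
#' use the particle engine.
#'
#' @param model a \linkS4class{PobdsModel} (Gaussian family).
#' @param traj a \linkS4class{Trajectory} or a T x n observation matrix.
#' @param prior optional initial belief over the 2^n states; defaults to
#'   \code{steadyState(model)}.
#' @param trace if TRUE return the full \linkS4class{FilterTrace} instead of
#'   the scalar log-likelihood.
#' @return the log-likelihood (or a \linkS4class{FilterTrace}).
#' @export
exactLogLik <- function(model, traj, prior = NULL, trace = FALSE) {
  y <- if (is(traj, "Trajectory")) traj@y else as.matrix(traj)
  n <- nGenes(model)
  checkMatrixGuard(n, "exact likelihood computation")
  if (model@noiseFamily != "gaussian")
    capabilityError("the exact engine supports the Gaussian observation family only")
  if (ncol(y) != n) stop("trajectory gene count does not match the model")
  if (is.null(prior)) prior <- steadyState(model, method = "exact")
  belief <- as.numeric(prior)
  M <- transitionMatrix(model)
  T_ <- nrow(y)
  incs <- numeric(T_)
  beliefs <- matrix(NA_real_, 2^n, T_)
  for (k in seq_len(T_)) {
    st <- bkfStep(belief, M, updateDiagonal(model, y[k, ]))
    belief <- as.numeric(st$belief)
    incs[k] <- st$logIncrement
    beliefs[, k] <- belief
  }
  if (trace)
    new("FilterTrace", beliefs = beliefs, logIncrements = incs,
        logLikelihood = sum(incs))
  else sum(incs)
}

#' Enumeration oracle for the trajectory log-likelihood
#'
#' Computes the trajectory marginal by explicit summation over all 2^(nT)
#' latent state sequences, with transition probabilities and observation
#' densities evaluated directly from their definitions (independently of the
#' matrix filter code path). Only feasible for n*T <= 20; used to validate
#' the filter recursion.
#'
#' @inheritParams exactLogLik
#' @return the log-likelihood.
#' @export
bruteForceLogLik <- function(model, traj, prior = NULL) {
  y <- if (is(traj, "Trajectory")) traj@y else as.matrix(traj)
  n <- nGenes(model)
  T_ <- nrow(y)
  if (n * T_ > 20) stop("enumeration bound exceeded: n*T must be <= 20")
  if (model@noiseFamily != "gaussian")
    capabilityError("the enumeration oracle supports the Gaussian observation family only")
  if (is.null(prior)) prior <- steadyState(model, method = "exact")
  nS <- 2^n
  S <- stateMatrix(n)
  f <- .evalStatesR(model@net, S)
  free <- setdiff(seq_len(n), match(names(model@net@frozen), geneNames(model)))
  # logTrans[i, j] = log P(x^i | x^j); perturbation acts on free genes only
  logTrans <- vapply(seq_len(nS), function(j) {
    diffs <- S != matrix(f[j, ], nS, n, byrow = TRUE)
    dH <- rowSums(diffs[, free, drop = FALSE])
    lt <- dH * log(model@p) + (length(free) - dH) * log(1 - model@p)
    if (length(free) < n)
      lt[rowSums(diffs[, -free, drop = FALSE]) > 0] <- -Inf
    lt
  }, numeric(nS))
  # logEmit[k, i] = log p(y_k | x^i)
  logEmit <- vapply(seq_len(nS), function(i) {
    mu <- model@lambda + model@delta * S[i, ]
    vapply(seq_len(T_), function(k) sum(dnorm(y[k, ], mu, model@sigma, log = TRUE)),
           numeric(1))
  }, numeric(T_))
  logEmit <- matrix(logEmit, nrow = T_)
  # x0 ~ prior is marginalized analytically into the time-1 state law
  logInit <- log(as.numeric(exp(logTrans) %*% as.numeric(prior)))
  idx <- as.matrix(expand.grid(rep(list(seq_len(nS)), T_)))
  lp <- logInit[idx[, 1]] + logEmit[1, idx[, 1]]
  if (T_ > 1) for (k in 2:T_) {
    lp <- lp + logTrans[cbind(idx[, k], idx[, k - 1])] + logEmit[k, idx[, k]]
  }
  logSumExp(lp)
}

#' Export a filter trace to CSV
#'
#' Writes the per-step log-likelihood increments (one row per time step) for
#' debugging and cross-engine comparison.
#'
#' @param trace a \linkS4class{FilterTrace}.
#' @param path output CSV path.
#' @export
writeFilterTrace <- function(trace, path) {
  df <- data.frame(time = seq_along(trace@logIncrements),
                   logIncrement = trace@logIncrements)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "FilterTrace", function(object) {
  cat(sprintf("FilterTrace: %d steps over %d states, logLik = %.6f\n",
              length(object@logIncrements), nrow(object@beliefs),
              object@logLikelihood))
})
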