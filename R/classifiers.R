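## Trajectory classifiers under regulatory model uncertainty: the optimal
## Bayesian classifier (OBC), the intrinsically Bayesian robust (IBR)
## classifier, the plug-in (per-class maximum-likelihood model) classifier,
## and the multiple-cell OBC on averaged expression samples. All arithmetic
## is in log space.

#' Construct an uncertainty class
#'
#' @param models0,models1 lists of M \linkS4class{PobdsModel} objects for the
#'   healthy (0) and cancerous (1) classes.
#' @param prior0,prior1 model prior weights per class; default uniform.
#' @param p0 prior probability of class 0 (default 0.5).
#' @return an \linkS4class{UncertaintyClass}.
#' @export
uncertaintyClass <- function(models0, models1, prior0 = NULL, prior1 = NULL,
                             p0 = 0.5) {
  M <- length(models0)
  if (is.null(prior0)) prior0 <- rep(1 / M, M)
  if (is.null(prior1)) prior1 <- rep(1 / M, M)
  new("UncertaintyClass", models0 = models0, models1 = models1,
      prior0 = prior0, prior1 = prior1, p0 = p0)
}

#' Construct a training set of labeled trajectories
#'
#' @param class0,class1 lists of \linkS4class{Trajectory} objects.
#' @return a \linkS4class{TrainingSet}.
#' @export
trainingSet <- function(class0 = list(), class1 = list()) {
  new("TrainingSet", class0 = class0, class1 = class1)
}

setMethod("show", "UncertaintyClass", function(object) {
  cat(sprintf("UncertaintyClass: M = %d models per class, p0 = %g\n",
              length(object@models0), object@p0))
  cat("  class 0:", paste(vapply(object@models0, slot, "", "modelId"), collapse = ", "), "\n")
  cat("  class 1:", paste(vapply(object@models1, slot, "", "modelId"), collapse = ", "), "\n")
})

# per-class training log-marginals: logMarg[theta] = sum_d L_theta(traj_d)
.trainLogMarginals <- function(models, trajs, engine, seed, classIdx) {
  vapply(seq_along(models), function(m) {
    if (!length(trajs)) return(0)
    sum(engineLogLik(engine, models[[m]], trajs,
                     seed = if (is.null(seed)) NULL else childSeed(seed, classIdx, m)))
  }, numeric(1))
}

.softmax <- function(lp) {
  w <- exp(lp - max(lp))
  w / sum(w)
}

#' Posterior over the uncertainty class given training trajectories
#'
#' For each class and candidate model the training log-marginal is the sum
#' of the trajectory log-likelihoods (training trajectories are
#' independent); the posterior model weights are the softmax of
#' log-marginal + log prior, computed with log-sum-exp. An empty training
#' class degrades to the prior (so the OBC coincides with the IBR
#' classifier).
#'
#' @param uc an \linkS4class{UncertaintyClass}.
#' @param train a \linkS4class{TrainingSet}.
#' @param engine a likelihood engine (see \code{\link{exactEngine}}).
#' @param seed integer seed split across (class, model) for particle engines.
#' @return a \linkS4class{ModelPosterior}.
#' @export
fitPosterior <- function(uc, train, engine, seed = NULL) {
  lm0 <- .trainLogMarginals(uc@models0, train@class0, engine, seed, 1L)
  lm1 <- .trainLogMarginals(uc@models1, train@class1, engine, seed, 2L)
  new("ModelPosterior",
      logMarginals0 = lm0, logMarginals1 = lm1,
      posterior0 = .softmax(lm0 + log(uc@prior0)),
      posterior1 = .softmax(lm1 + log(uc@prior1)))
}

# log tau^c for a matrix of test log-likelihoods (rows = trajectories,
# columns = models) under model weights w (prior or posterior)
.logTau <- function(L, w) {
  lw <- log(w)
  apply(L, 1L, function(r) logSumExp(r + lw))
}

.decision <- function(score0, score1, classifier) {
  lab <- ifelse(score0 >= score1, 0L, 1L)
  new("ClassifierDecision", label = lab,
      logScores = c(class0 = score0, class1 = score1),
      classifier = classifier)
}

# test log-likelihood row vector per class: L[1, theta]
.testLogLik <- function(models, test, engine, seed, classIdx) {
  vapply(seq_along(models), function(m) {
    engineLogLik(engine, models[[m]], test,
                 seed = if (is.null(seed)) NULL else childSeed(seed, 100L + classIdx, m))
  }, numeric(1))
}

#' Optimal Bayesian classification of a test trajectory
#'
#' Scores each class by its prior-weighted posterior-expected trajectory
#' density: \code{score_c = log p_c + logsumexp_theta(log posterior(theta|c)
#' + L_c^theta(test))}, and labels class 0 on ties (the decision rule's >=).
#'
#' @param uc an \linkS4class{UncertaintyClass}.
#' @param post a \linkS4class{ModelPosterior} from \code{\link{fitPosterior}}
#'   on the same uncertainty class.
#' @param test a test \linkS4class{Trajectory} (or T x n matrix).
#' @param engine a likelihood engine.
#' @param seed integer seed for particle engines.
#' @return a \linkS4class{ClassifierDecision}.
#' @export
obcClassify <- function(uc, post, test, engine, seed = NULL) {
  L0 <- .testLogLik(uc@models0, test, engine, seed, 1L)
  L1 <- .testLogLik(uc@models1, test, engine, seed, 2L)
  .decision(log(uc@p0) + logSumExp(L0 + log(post@posterior0)),
            log(1 - uc@p0) + logSumExp(L1 + log(post@posterior1)),
            "obc")
}

#' Intrinsically Bayesian robust classification
#'
#' Identical to \code{\link{obcClassify}} with the expectation taken under
#' the prior model weights; uses no training data.
#'
#' @inheritParams obcClassify
#' @return a \linkS4class{ClassifierDecision}.
#' @export
ibrClassify <- function(uc, test, engine, seed = NULL) {
  L0 <- .testLogLik(uc@models0, test, engine, seed, 1L)
  L1 <- .testLogLik(uc@models1, test, engine, seed, 2L)
  .decision(log(uc@p0) + logSumExp(L0 + log(uc@prior0)),
            log(1 - uc@p0) + logSumExp(L1 + log(uc@prior1)),
            "ibr")
}

#' Plug-in classification
#'
#' Per class, selects the maximum-training-likelihood model (ties break to
#' the lowest model index) and applies the Bayes rule at that estimate.
#'
#' @inheritParams obcClassify
#' @param train a \linkS4class{TrainingSet}.
#' @return a \linkS4class{ClassifierDecision}.
#' @export
pluginClassify <- function(uc, train, test, engine, seed = NULL) {
  lm0 <- .trainLogMarginals(uc@models0, train@class0, engine, seed, 1L)
  lm1 <- .trainLogMarginals(uc@models1, train@class1, engine, seed, 2L)
  m0 <- which.max(lm0)
  m1 <- which.max(lm1)
  s0 <- log(uc@p0) + engineLogLik(engine, uc@models0[[m0]], test,
                                  seed = if (is.null(seed)) NULL else childSeed(seed, 100L + 1L, m0))
  s1 <- log(1 - uc@p0) + engineLogLik(engine, uc@models1[[m1]], test,
                                      seed = if (is.null(seed)) NULL else childSeed(seed, 100L + 2L, m1))
  .decision(s0, s1, "plugin")
}

## ---- multiple-cell (averaged expression) classification -------------------

# marginal ON probability per gene under the steady state
.steadyMarginals <- function(model, ssPool = NULL) {
  n <- nGenes(model)
  if (!is.null(ssPool)) return(colMeans(ssPool))
  if (n > .matrixGuard())
    capabilityError("steady-state marginals for large networks need a Monte-Carlo pool (ssPool)")
  pi <- as.numeric(steadyState(model, method = "exact"))
  as.numeric(t(stateMatrix(n)) %*% pi)
}

#' Multiple-cell sample log-density
#'
#' Under averaged multiple-cell measurement, each gene's expression is a
#' two-component Gaussian mixture: gene j is ON with its steady-state
#' marginal probability \code{q_j}, so
#' \code{y_j ~ (1-q_j) N(lambda_j, sigma^2) + q_j N(lambda_j + delta_j,
#' sigma^2)} and genes are independent. Returns the log-density of one
#' sample.
#'
#' @param model a \linkS4class{PobdsModel} (Gaussian family).
#' @param y an expression vector of length n (or an m x n matrix of samples).
#' @param ssPool optional Monte-Carlo steady-state pool for networks beyond
#'   the matrix guard.
#' @return log-density (vector of length m for a matrix input).
#' @export
multicellDensity <- function(model, y, ssPool = NULL) {
  q <- .steadyMarginals(model, ssPool)
  ym <- if (is.null(dim(y))) matrix(as.numeric(y), nrow = 1) else as.matrix(y)
  if (ncol(ym) != nGenes(model)) stop("sample gene count does not match the model")
  out <- vapply(seq_len(nrow(ym)), function(i) {
    la <- dnorm(ym[i, ], model@lambda, model@sigma, log = TRUE) + log1p(-q)
    lb <- dnorm(ym[i, ], model@lambda + model@delta, model@sigma, log = TRUE) + log(q)
    sum(pmax(la, lb) + log1p(exp(-abs(la - lb))))
  }, numeric(1))
  if (is.null(dim(y))) out[1] else out
}

#' Simulate multiple-cell expression samples
#'
#' Each sample's latent Boolean state is drawn independently from the
#' model's steady-state distribution, then observed through the Gaussian
#' channel (matching the independence assumption of the multiple-cell
#' measurement model).
#'
#' @param model a \linkS4class{PobdsModel}.
#' @param nSamples number of samples.
#' @param ssPool optional steady-state pool.
#' @param seed optional integer seed.
#' @return an nSamples x n expression matrix.
#' @export
sampleMulticell <- function(model, nSamples, ssPool = NULL, seed = NULL) {
  withSeed(seed, {
    x <- .drawInitialStates(model, nSamples, ssPool)
    mu <- matrix(model@lambda, nSamples, nGenes(model), byrow = TRUE) +
      x * matrix(model@delta, nSamples, nGenes(model), byrow = TRUE)
    y <- mu + matrix(stats::rnorm(length(mu), 0, model@sigma), nrow = nSamples)
    colnames(y) <- geneNames(model)
    y
  })
}

#' Multiple-cell optimal Bayesian classification
#'
#' The OBC on single averaged-expression samples: per class, the posterior
#' over candidate models is proportional to the product of the mixture
#' densities of the training samples times the prior; the decision weighs
#' the posterior-expected test density by the class priors, labelling class
#' 0 on ties.
#'
#' @param uc an \linkS4class{UncertaintyClass} (Gaussian family models).
#' @param train0,train1 training sample matrices (rows are samples; either
#'   may have zero rows, degrading that class's posterior to the prior).
#' @param y the test expression vector.
#' @param ssPools optional list of two lists of steady-state pools (class 0,
#'   class 1) aligned with the models, for networks beyond the matrix guard.
#' @return a \linkS4class{ClassifierDecision}.
#' @export
multicellObc <- function(uc, train0, train1, y, ssPools = NULL) {
  scoreClass <- function(models, prior, train, pools) {
    ltrain <- vapply(seq_along(models), function(m) {
      if (is.null(train) || !nrow(train)) 0
      else sum(multicellDensity(models[[m]], train,
                                ssPool = if (is.null(pools)) NULL else pools[[m]]))
    }, numeric(1))
    post <- .softmax(ltrain + log(prior))
    ltest <- vapply(seq_along(models), function(m) {
      multicellDensity(models[[m]], y,
                       ssPool = if (is.null(pools)) NULL else pools[[m]])
    }, numeric(1))
    logSumExp(ltest + log(post))
  }
  train0 <- if (is.null(train0)) matrix(numeric(), 0, nGenes(uc@models0[[1]])) else as.matrix(train0)
  train1 <- if (is.null(train1)) matrix(numeric(), 0, nGenes(uc@models1[[1]])) else as.matrix(train1)
  s0 <- log(uc@p0) + scoreClass(uc@models0, uc@prior0, train0,
                                if (is.null(ssPools)) NULL else ssPools[[1]])
  s1 <- log(1 - uc@p0) + scoreClass(uc@models1, uc@prior1, train1,
                                    if (is.null(ssPools)) NULL else ssPools[[2]])
  .decision(s0, s1, "multicell_obc")
}

setMethod("show", "ClassifierDecision", function(object) {
  cat(sprintf("%s decision: class %d (log-scores: %.4f vs %.4f)\n",
              object@classifier, object@label,
              object@logScores[1], object@logScores[2]))
})

setMethod("show", "ModelPosterior", function(object) {
  cat("ModelPosterior\n")
  cat("  class 0:", paste(sprintf("%.4f", object@posterior0), collapse = " "), "\n")
  cat("  class 1:", paste(sprintf("%.4f", object@posterior1), collapse = " "), "\n")
})
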