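#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats dnorm dpois dnbinom rbinom runif setNames sd
#' @importFrom utils head read.csv write.csv
NULL

#' Boolean gene regulatory network
#'
#' A Boolean network over \code{n} named genes. Each gene carries one Boolean
#' update rule (an expression over gene names using NOT/AND/OR); optionally a
#' gene can be frozen at a constant, overriding its rule — this is how a
#' mutation such as "Apoptosis stuck at OFF" is represented without rewriting
#' the shared rule set.
#'
#' @slot geneNames ordered character vector of gene identifiers; gene 1 is the
#'   least-significant bit of the canonical state index.
#' @slot rules named list of R language objects (one per gene) using
#'   \code{!}, \code{&}, \code{|} over gene names and the literals 0/1.
#' @slot ruleText the normalized one-line-per-gene textual rules.
#' @slot frozen named integer vector (values 0 or 1) of frozen genes; may be
#'   empty.
#' @export
setClass("BooleanNetwork",
  representation(geneNames = "character", rules = "list",
                 ruleText = "character", frozen = "integer"))

setValidity("BooleanNetwork", function(object) {
  gn <- object@geneNames
  if (length(gn) < 1L) return("network needs at least one gene")
  if (anyDuplicated(gn)) return("duplicate gene names")
  if (!identical(names(object@rules), gn)) return("rules must be named by geneNames, in order")
  for (g in gn) {
    vars <- all.vars(object@rules[[g]])
    bad <- setdiff(vars, gn)
    if (length(bad))
      return(sprintf("rule for '%s' references undefined identifier(s): %s",
                     g, paste(bad, collapse = ", ")))
  }
  if (length(object@frozen)) {
    if (is.null(names(object@frozen)) || !all(names(object@frozen) %in% gn))
      return("frozen genes must be named and declared")
    if (!all(object@frozen %in% c(0L, 1L))) return("frozen values must be 0 or 1")
  }
  TRUE
})

#' Partially-observed Boolean dynamical system model
#'
#' Couples a Boolean network with the two noise channels of the POBDS model:
#' Bernoulli state-perturbation noise of intensity \code{p} (each gene's
#' updated bit is flipped independently with probability p) and an
#' observation channel in which gene j is measured as baseline
#' \code{lambda[j]} plus differential expression \code{delta[j]} when ON,
#' corrupted by Gaussian (sd \code{sigma}), Poisson, or negative-binomial
#' noise.
#'
#' @slot net a \linkS4class{BooleanNetwork}.
#' @slot p Bernoulli perturbation probability, in (0, 0.5).
#' @slot lambda baseline expression per gene (length n).
#' @slot delta differential expression per gene (length n).
#' @slot sigma observation noise standard deviation (Gaussian / NB families).
#' @slot noiseFamily one of "gaussian", "poisson", "negative_binomial".
#' @slot modelId character label used for caching and reporting.
#' @export
setClass("PobdsModel",
  representation(net = "BooleanNetwork", p = "numeric", lambda = "numeric",
                 delta = "numeric", sigma = "numeric", noiseFamily = "character",
                 modelId = "character"))

setValidity("PobdsModel", function(object) {
  n <- length(object@net@geneNames)
  if (length(object@p) != 1L || is.na(object@p) || object@p <= 0 || object@p >= 0.5)
    return("p must satisfy 0 < p < 0.5")
  if (length(object@lambda) != n) return("lambda must have one entry per gene")
  if (length(object@delta) != n) return("delta must have one entry per gene")
  if (!object@noiseFamily %in% c("gaussian", "poisson", "negative_binomial"))
    return("noiseFamily must be gaussian, poisson or negative_binomial")
  if (object@noiseFamily != "poisson") {
    if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma <= 0)
      return("sigma must be a positive scalar")
  }
  if (object@noiseFamily == "negative_binomial") {
    if (object@sigma^2 <= max(object@lambda + pmax(object@delta, 0)))
      return("negative binomial requires sigma^2 > mean for every state (overdispersion)")
  }
  TRUE
})

#' Belief vector over the 2^n Boolean states
#'
#' A probability vector indexed by the canonical state encoding
#' (index = 1 + sum_j x_j 2^(j-1)).
#' @export
setClass("BeliefVector", contains = "numeric")

setValidity("BeliefVector", function(object) {
  v <- as.numeric(object)
  if (any(v < 0)) return("belief entries must be nonnegative")
  if (abs(sum(v) - 1) > 1e-10) return("belief entries must sum to 1 (tol 1e-10)")
  n2 <- length(v)
  if (n2 < 2 || bitwAnd(n2, n2 - 1L) != 0L) return("length must be a power of 2")
  TRUE
})

#' Single-cell expression trajectory
#'
#' @slot y T x n real matrix of observations (columns named by genes).
#' @slot x optional T x n Boolean latent state matrix (0 rows when absent).
#' @slot meta list of metadata (class label, model id, seed, ...).
#' @export
setClass("Trajectory",
  representation(y = "matrix", x = "matrix", meta = "list"))

setValidity("Trajectory", function(object) {
  if (nrow(object@y) < 1L) return("trajectory needs at least one time step")
  if (nrow(object@x) > 0L && !identical(dim(object@x), dim(object@y)))
    return("latent states x must have the same shape as y")
  TRUE
})

#' Boolean Kalman filter trace
#'
#' Per-step posterior beliefs and log-likelihood increments of the exact
#' filter recursion.
#'
#' @slot beliefs 2^n x T matrix; column k is the filtering distribution at k.
#' @slot logIncrements length-T vector of per-step log normalizers.
#' @slot logLikelihood their sum.
#' @export
setClass("FilterTrace",
  representation(beliefs = "matrix", logIncrements = "numeric",
                 logLikelihood = "numeric"))

setValidity("FilterTrace", function(object) {
  if (ncol(object@beliefs) != length(object@logIncrements))
    return("one belief column per log increment required")
  if (max(abs(colSums(object@beliefs) - 1)) > 1e-10)
    return("each belief must sum to 1 (tol 1e-10)")
  if (!isTRUE(all.equal(object@logLikelihood, sum(object@logIncrements))))
    return("logLikelihood must equal the sum of logIncrements")
  TRUE
})

#' Weighted Boolean particle ensemble
#'
#' @slot states N x n integer 0/1 matrix of particle states.
#' @slot weights length-N nonnegative weights (kept normalized to mean 1).
#' @slot auxProbs first-stage (look-ahead) probabilities of the most recent
#'   auxiliary-particle-filter step, normalized to sum 1; empty before the
#'   first step.
#' @export
setClass("ParticleEnsemble",
  representation(states = "matrix", weights = "numeric", auxProbs = "numeric"))

setValidity("ParticleEnsemble", function(object) {
  N <- nrow(object@states)
  if (N < 1L) return("need at least one particle")
  if (length(object@weights) != N) return("one weight per particle required")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    return("weights must be finite and nonnegative")
  if (all(object@weights == 0)) return("weights must not all be zero")
  if (!all(object@states %in% c(0L, 1L))) return("particle states must be 0/1")
  TRUE
})

#' Uncertainty class of candidate regulatory network models
#'
#' M candidate POBDS models per class label (0 = healthy, 1 = cancerous) with
#' prior model weights per class and a prior class-0 probability.
#'
#' @slot models0,models1 lists of M \linkS4class{PobdsModel} objects.
#' @slot prior0,prior1 per-class model priors, each summing to 1.
#' @slot p0 prior probability of class 0.
#' @export
setClass("UncertaintyClass",
  representation(models0 = "list", models1 = "list",
                 prior0 = "numeric", prior1 = "numeric", p0 = "numeric"))

setValidity("UncertaintyClass", function(object) {
  M <- length(object@models0)
  if (M < 1L) return("need at least one model per class")
  if (length(object@models1) != M) return("both classes must have the same number of models")
  if (!all(vapply(c(object@models0, object@models1), is, logical(1), "PobdsModel")))
    return("models must be PobdsModel objects")
  for (pr in list(object@prior0, object@prior1)) {
    if (length(pr) != M) return("one prior weight per model required")
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-10) return("model priors must be nonnegative and sum to 1")
  }
  if (object@p0 < 0 || object@p0 > 1) return("p0 must lie in [0, 1]")
  TRUE
})

#' Labeled training trajectories
#'
#' @slot class0,class1 lists of \linkS4class{Trajectory} objects per class;
#'   either may be empty, in which case posterior weighting degrades to the
#'   prior.
#' @export
setClass("TrainingSet",
  representation(class0 = "list", class1 = "list"))

setValidity("TrainingSet", function(object) {
  traj <- c(object@class0, object@class1)
  if (length(traj) && !all(vapply(traj, is, logical(1), "Trajectory")))
    return("training sets must contain Trajectory objects")
  TRUE
})

#' Posterior over the uncertainty class given training data
#'
#' @slot logMarginals0,logMarginals1 per-model summed training log-likelihoods.
#' @slot posterior0,posterior1 normalized posterior model weights per class.
#' @export
setClass("ModelPosterior",
  representation(logMarginals0 = "numeric", logMarginals1 = "numeric",
                 posterior0 = "numeric", posterior1 = "numeric"))

setValidity("ModelPosterior", function(object) {
  for (po in list(object@posterior0, object@posterior1))
    if (any(po < 0) || abs(sum(po) - 1) > 1e-10)
      return("posteriors must be nonnegative and sum to 1 (tol 1e-10)")
  if (length(object@posterior0) != length(object@logMarginals0) ||
      length(object@posterior1) != length(object@logMarginals1))
    return("posterior and logMarginals lengths must agree")
  TRUE
})

#' Binary classification decision
#'
#' @slot label 0 or 1; ties in the log-scores resolve to class 0.
#' @slot logScores named length-2 vector: log class prior plus log
#'   (posterior-)expected trajectory density per class.
#' @slot classifier one of "obc", "ibr", "plugin", "multicell_obc".
#' @export
setClass("ClassifierDecision",
  representation(label = "integer", logScores = "numeric", classifier = "character"))

setValidity("ClassifierDecision", function(object) {
  if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
  if (length(object@logScores) != 2L) return("need one log-score per class")
  s <- object@logScores
  want <- if (s[1] >= s[2]) 0L else 1L
  if (!is.na(want) && object@label != want)
    return("label must be 0 iff the class-0 log-score is >= the class-1 log-score")
  TRUE
})
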