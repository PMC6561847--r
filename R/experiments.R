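## Seeded scenario runner: simulate trajectory classification experiments
## under the T-LGL uncertainty class (or custom models), estimate
## misclassification rates across replicates, and sweep design axes.

#' Scenario configuration
#'
#' Bundles every knob of one classification experiment. Defaults follow the
#' simulation design used throughout the package: the T-LGL network pair
#' (healthy vs Apoptosis-frozen) generates the data, the uncertainty class
#' holds the first \code{M} T-LGL variants per class, \code{lambda = 10},
#' \code{delta = 30}, \code{D = D0 + D1 = 4} training trajectories,
#' \code{N = 1000} particles, balanced test pools and uniform priors.
#'
#' @slot variants T-LGL variant labels used for the uncertainty class.
#' @slot M number of candidate models per class.
#' @slot p Bernoulli perturbation probability.
#' @slot lambda,delta,sigma observation model parameters (scalars).
#' @slot noiseFamily observation noise family.
#' @slot T trajectory length.
#' @slot D0,D1 training trajectories per class.
#' @slot N particle count for the particle engines.
#' @slot engine "apf", "exact" or "sir".
#' @slot classifiers subset of c("obc", "ibr", "plugin", "multicell_obc").
#' @slot nReps replicates (training data regenerated each time).
#' @slot nTestPerClass test trajectories per class per replicate.
#' @slot seed root seed; all randomness derives from it via
#'   \code{\link{childSeed}}.
#' @slot ssPoolSize Monte-Carlo steady-state pool size for large networks.
#' @slot customUC optional \linkS4class{UncertaintyClass} overriding the
#'   T-LGL construction.
#' @slot customTrue optional list of the two generating models (class 0,
#'   class 1) used with \code{customUC}.
#' @export
setClass("ScenarioConfig",
  representation(variants = "character", M = "integer", p = "numeric",
                 lambda = "numeric", delta = "numeric", sigma = "numeric",
                 noiseFamily = "character", T = "integer", D0 = "integer",
                 D1 = "integer", N = "integer", engine = "character",
                 classifiers = "character", nReps = "integer",
                 nTestPerClass = "integer", seed = "integer",
                 ssPoolSize = "integer", customUC = "ANY", customTrue = "list"))

setValidity("ScenarioConfig", function(object) {
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (object@nTestPerClass < 1L) return("nTestPerClass must be >= 1")
  if (object@T < 1L) return("T must be >= 1")
  if (object@N < 1L) return("N must be >= 1")
  if (object@D0 < 0L || object@D1 < 0L) return("D0/D1 must be >= 0")
  if (!object@engine %in% c("apf", "exact", "sir")) return("unknown engine")
  if (!all(object@classifiers %in% c("obc", "ibr", "plugin", "multicell_obc")))
    return("unknown classifier id")
  TRUE
})

#' @rdname ScenarioConfig-class
#' @param T,p,sigma,lambda,delta,noiseFamily,M,N,engine,classifiers,nReps,nTestPerClass,seed,ssPoolSize
#'   see the class slots.
#' @param D total training trajectories, split equally (D0 = D1 = D/2)
#'   unless D0/D1 are given explicitly.
#' @param D0,D1 per-class training counts.
#' @param customUC,customTrue optional custom uncertainty class and
#'   generating model pair.
#' @return a \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(T = 3L, p = 0.05, sigma = 25, lambda = 10, delta = 30,
                           noiseFamily = "gaussian", M = 4L, D = 4L,
                           D0 = NULL, D1 = NULL, N = 1000L,
                           engine = c("apf", "exact", "sir"),
                           classifiers = c("obc", "ibr", "plugin"),
                           nReps = 50L, nTestPerClass = 200L, seed = 1L,
                           ssPoolSize = 10000L,
                           customUC = NULL, customTrue = list()) {
  engine <- match.arg(engine)
  if (is.null(D0)) D0 <- as.integer(D) %/% 2L
  if (is.null(D1)) D1 <- as.integer(D) - as.integer(D0)
  new("ScenarioConfig", variants = c("true", "v2", "v3", "v4"),
      M = as.integer(M), p = as.numeric(p), lambda = as.numeric(lambda),
      delta = as.numeric(delta), sigma = as.numeric(sigma),
      noiseFamily = noiseFamily, T = as.integer(T), D0 = as.integer(D0),
      D1 = as.integer(D1), N = as.integer(N), engine = engine,
      classifiers = classifiers, nReps = as.integer(nReps),
      nTestPerClass = as.integer(nTestPerClass), seed = as.integer(seed),
      ssPoolSize = as.integer(ssPoolSize), customUC = customUC,
      customTrue = customTrue)
}

#' Read a scenario configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{scenarioConfig}}; the particle
#' count is accepted as \code{particles} (a bare \code{N} key is a boolean
#' in YAML, so use \code{particles} or quote the key).
#'
#' @param path YAML file path.
#' @return a \linkS4class{ScenarioConfig}.
#' @export
readScenarioConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  names(vals)[names(vals) == "particles"] <- "N"
  names(vals)[names(vals) == "FALSE"] <- "N"   # an unquoted N key
  ok <- intersect(names(vals), names(formals(scenarioConfig)))
  do.call(scenarioConfig, vals[ok])
}

.configHash <- function(cfg) {
  paste(cfg@engine, cfg@M, cfg@p, cfg@sigma, cfg@T, cfg@D0, cfg@D1, cfg@N,
        cfg@noiseFamily, cfg@nReps, cfg@nTestPerClass, cfg@seed, sep = "_")
}

# resolve the uncertainty class, the generating (true) models, the engine and
# the steady-state pools of one scenario
.scenarioContext <- function(cfg) {
  if (!is.null(cfg@customUC)) {
    uc <- cfg@customUC
    if (length(cfg@customTrue) != 2L)
      stop("customUC requires customTrue = list(model0, model1)")
    true0 <- cfg@customTrue[[1]]
    true1 <- cfg@customTrue[[2]]
  } else {
    uc <- tlglUncertaintyClass(M = cfg@M, p = cfg@p, lambda = cfg@lambda,
                               delta = cfg@delta, sigma = cfg@sigma,
                               noiseFamily = cfg@noiseFamily)
    true0 <- pobdsModel(tlglNetwork("true", "healthy"), p = cfg@p,
                        lambda = cfg@lambda, delta = cfg@delta,
                        sigma = cfg@sigma, noiseFamily = cfg@noiseFamily,
                        modelId = "tlgl_true_healthy")
    true1 <- pobdsModel(tlglNetwork("true", "mutated"), p = cfg@p,
                        lambda = cfg@lambda, delta = cfg@delta,
                        sigma = cfg@sigma, noiseFamily = cfg@noiseFamily,
                        modelId = "tlgl_true_mutated")
  }
  engine <- switch(cfg@engine,
    exact = exactEngine(),
    apf = apfEngine(cfg@N, cfg@ssPoolSize, poolSeed = childSeed(cfg@seed, 950L)),
    sir = sirEngine(cfg@N, cfg@ssPoolSize, poolSeed = childSeed(cfg@seed, 950L)))
  big <- nGenes(true0) > .matrixGuard()
  pool0 <- if (big) steadyStatePool(true0, cfg@ssPoolSize,
                                    seed = childSeed(cfg@seed, 901L)) else NULL
  pool1 <- if (big) steadyStatePool(true1, cfg@ssPoolSize,
                                    seed = childSeed(cfg@seed, 902L)) else NULL
  list(uc = uc, true0 = true0, true1 = true1, engine = engine,
       pool0 = pool0, pool1 = pool1, big = big)
}

.asTrajList <- function(x) if (is.list(x)) x else list(x)

#' Generate the data of one scenario replicate
#'
#' Simulates \code{D0}/\code{D1} training trajectories and a balanced test
#' pool (\code{nTestPerClass} per class) from the scenario's two generating
#' models, deterministically seeded from \code{(seed, repIndex)}.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @param repIndex replicate index (>= 1).
#' @return list with \code{train} (a \linkS4class{TrainingSet}) and
#'   \code{test0}, \code{test1} (lists of \linkS4class{Trajectory}).
#' @export
generateScenarioData <- function(cfg, repIndex) {
  ctx <- .scenarioContext(cfg)
  .generateData(ctx, cfg, repIndex)
}

.generateData <- function(ctx, cfg, repIndex) {
  sim <- function(model, m, pool, tag) {
    if (m == 0L) return(list())
    .asTrajList(simulateTrajectory(model, cfg@T, nTraj = m, ssPool = pool,
                                   seed = childSeed(cfg@seed, repIndex, tag)))
  }
  list(train = trainingSet(sim(ctx$true0, cfg@D0, ctx$pool0, 1L),
                           sim(ctx$true1, cfg@D1, ctx$pool1, 2L)),
       test0 = sim(ctx$true0, cfg@nTestPerClass, ctx$pool0, 3L),
       test1 = sim(ctx$true1, cfg@nTestPerClass, ctx$pool1, 4L))
}

# row-wise logsumexp of L with per-column log-weights lw
.rowLogSumExp <- function(L, lw) {
  A <- sweep(L, 2L, lw, "+")
  m <- apply(A, 1L, max)
  m + log(rowSums(exp(A - m)))
}

# one replicate: shared log-likelihood matrices feed all trajectory
# classifiers; returns named error vector
.runReplicate <- function(ctx, cfg, repIndex) {
  uc <- ctx$uc
  M <- length(uc@models0)
  dat <- .generateData(ctx, cfg, repIndex)
  test <- c(dat$test0, dat$test1)
  truth <- rep(c(0L, 1L), c(length(dat$test0), length(dat$test1)))
  engine <- ctx$engine

  trajCls <- intersect(cfg@classifiers, c("obc", "ibr", "plugin"))
  errs <- c()
  if (length(trajCls)) {
    lm0 <- vapply(seq_len(M), function(m)
      if (length(dat$train@class0))
        sum(engineLogLik(engine, uc@models0[[m]], dat$train@class0,
                         seed = childSeed(cfg@seed, repIndex, 10L, 1L, m))) else 0,
      numeric(1))
    lm1 <- vapply(seq_len(M), function(m)
      if (length(dat$train@class1))
        sum(engineLogLik(engine, uc@models1[[m]], dat$train@class1,
                         seed = childSeed(cfg@seed, repIndex, 10L, 2L, m))) else 0,
      numeric(1))
    L0 <- vapply(seq_len(M), function(m)
      engineLogLik(engine, uc@models0[[m]], test,
                   seed = childSeed(cfg@seed, repIndex, 20L, 1L, m)),
      numeric(length(test)))
    L1 <- vapply(seq_len(M), function(m)
      engineLogLik(engine, uc@models1[[m]], test,
                   seed = childSeed(cfg@seed, repIndex, 20L, 2L, m)),
      numeric(length(test)))
    L0 <- matrix(L0, ncol = M)
    L1 <- matrix(L1, ncol = M)
    lp0 <- log(uc@p0)
    lp1 <- log(1 - uc@p0)
    score <- function(w0, w1) {
      s0 <- lp0 + .rowLogSumExp(L0, log(w0))
      s1 <- lp1 + .rowLogSumExp(L1, log(w1))
      mean(ifelse(s0 >= s1, 0L, 1L) != truth)
    }
    if ("obc" %in% trajCls) {
      post0 <- .softmax(lm0 + log(uc@prior0))
      post1 <- .softmax(lm1 + log(uc@prior1))
      errs["obc"] <- score(post0, post1)
    }
    if ("ibr" %in% trajCls)
      errs["ibr"] <- score(uc@prior0, uc@prior1)
    if ("plugin" %in% trajCls) {
      m0 <- which.max(lm0)
      m1 <- which.max(lm1)
      s0 <- lp0 + L0[, m0]
      s1 <- lp1 + L1[, m1]
      errs["plugin"] <- mean(ifelse(s0 >= s1, 0L, 1L) != truth)
    }
  }

  if ("multicell_obc" %in% cfg@classifiers) {
    # budget-matched per-sample design: T*D_c training samples per class
    n0 <- cfg@T * cfg@D0
    n1 <- cfg@T * cfg@D1
    tr0 <- if (n0) sampleMulticell(ctx$true0, n0, ssPool = ctx$pool0,
                                   seed = childSeed(cfg@seed, repIndex, 31L)) else NULL
    tr1 <- if (n1) sampleMulticell(ctx$true1, n1, ssPool = ctx$pool1,
                                   seed = childSeed(cfg@seed, repIndex, 32L)) else NULL
    te0 <- sampleMulticell(ctx$true0, cfg@nTestPerClass, ssPool = ctx$pool0,
                           seed = childSeed(cfg@seed, repIndex, 33L))
    te1 <- sampleMulticell(ctx$true1, cfg@nTestPerClass, ssPool = ctx$pool1,
                           seed = childSeed(cfg@seed, repIndex, 34L))
    teAll <- rbind(te0, te1)
    mtruth <- rep(c(0L, 1L), c(nrow(te0), nrow(te1)))
    if (is.null(ctx$qPools)) {
      # steady-state pools for the candidate models' marginals (large n only)
      ctx$qPools <- if (!ctx$big) NULL else list(
        lapply(seq_len(M), function(m) .enginePool(ctx$engine, uc@models0[[m]])),
        lapply(seq_len(M), function(m) .enginePool(ctx$engine, uc@models1[[m]])))
    }
    mscore <- function(models, prior, train, pools) {
      ltrain <- vapply(seq_len(M), function(m)
        if (is.null(train)) 0
        else sum(multicellDensity(models[[m]], train,
                                  ssPool = if (is.null(pools)) NULL else pools[[m]])),
        numeric(1))
      post <- .softmax(ltrain + log(prior))
      Lt <- vapply(seq_len(M), function(m)
        multicellDensity(models[[m]], teAll,
                         ssPool = if (is.null(pools)) NULL else pools[[m]]),
        numeric(nrow(teAll)))
      .rowLogSumExp(matrix(Lt, ncol = M), log(post))
    }
    s0 <- log(uc@p0) + mscore(uc@models0, uc@prior0, tr0,
                              if (ctx$big) ctx$qPools[[1]] else NULL)
    s1 <- log(1 - uc@p0) + mscore(uc@models1, uc@prior1, tr1,
                                  if (ctx$big) ctx$qPools[[2]] else NULL)
    errs["multicell_obc"] <- mean(ifelse(s0 >= s1, 0L, 1L) != mtruth)
  }
  errs
}

#' Estimate classification error over replicates
#'
#' Runs \code{nReps} independent replicates: each regenerates training data
#' from the true models, fits whatever each classifier needs (posterior
#' weights for the OBC, maximum-likelihood model selection for the plug-in),
#' classifies a balanced test pool and records the misclassification
#' fraction. A replicate in which a particle filter collapses is recorded as
#' failed and excluded (never silently).
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @param classifiers optionally override \code{cfg@classifiers}.
#' @return a data.frame with one row per classifier: mean error, sd across
#'   replicates, replicate and failure counts and the config hash. The full
#'   replicate-by-classifier error matrix is attached as
#'   \code{attr(, "replicates")} for paired comparisons.
#' @export
estimateError <- function(cfg, classifiers = NULL) {
  if (!is.null(classifiers)) cfg <- initialize(cfg, classifiers = classifiers)
  ctx <- .scenarioContext(cfg)
  reps <- vector("list", cfg@nReps)
  failed <- 0L
  for (r in seq_len(cfg@nReps)) {
    reps[[r]] <- tryCatch(.runReplicate(ctx, cfg, r), error = function(e) {
      if (grepl("collapse", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(reps[[r]])) failed <- failed + 1L
  }
  ok <- !vapply(reps, is.null, logical(1))
  em <- do.call(rbind, reps[ok])
  if (is.null(em)) stop("all replicates failed (particle filter collapse)")
  out <- data.frame(classifier = colnames(em),
                    meanError = colMeans(em),
                    sdError = apply(em, 2L, sd),
                    nReps = sum(ok), nFailed = failed,
                    configHash = .configHash(cfg),
                    row.names = NULL)
  attr(out, "replicates") <- em
  out
}

#' Reproduce the high-noise comparison grid
#'
#' Runs \{Plug-In, IBR, OBC\} over the grid p in \code{ps} x T in \code{Ts}
#' at sigma = 25 with the particle engine, mirroring the high-noise
#' trajectory-classification comparison, and returns one row per
#' (classifier, cell).
#'
#' @param cfg base \linkS4class{ScenarioConfig}; its p and T are overridden
#'   cell by cell (seeds are shared across cells for paired comparisons).
#' @param ps,Ts grid values.
#' @param verbose print progress per cell.
#' @return a data.frame of error estimates with columns p and T added.
#' @export
runTable2 <- function(cfg = scenarioConfig(sigma = 25), ps = c(0.05, 0.1),
                      Ts = c(3L, 7L), verbose = interactive()) {
  cfg <- initialize(cfg, sigma = 25,
                    classifiers = c("obc", "ibr", "plugin"))
  out <- list()
  repl <- list()
  for (p in ps) for (T_ in Ts) {
    cellCfg <- initialize(cfg, p = as.numeric(p), T = as.integer(T_))
    if (verbose) message(sprintf("cell p=%g T=%d ...", p, T_))
    est <- estimateError(cellCfg)
    est$p <- p
    est$T <- T_
    repl[[sprintf("p%g_T%d", p, T_)]] <- attr(est, "replicates")
    out[[length(out) + 1L]] <- est
  }
  res <- do.call(rbind, out)
  attr(res, "replicates") <- repl
  res
}

#' Sweep one design axis
#'
#' Re-estimates the classification error along a grid of one scenario
#' parameter (T, D, M, N, sigma or noise_family), sharing the root seed
#' across grid points so comparisons are paired.
#'
#' @param axis one of "T", "D", "M", "N", "sigma", "noise_family".
#' @param grid vector of axis values (D values are split equally between the
#'   classes).
#' @param cfg base \linkS4class{ScenarioConfig}.
#' @param verbose print progress.
#' @return a data.frame of error estimates with a \code{value} column; the
#'   per-grid-point replicate matrices are in \code{attr(, "replicates")}.
#' @export
runSweep <- function(axis = c("T", "D", "M", "N", "sigma", "noise_family"),
                     grid, cfg = scenarioConfig(), verbose = interactive()) {
  axis <- match.arg(axis)
  out <- list()
  repl <- list()
  for (g in grid) {
    cg <- switch(axis,
      T = initialize(cfg, T = as.integer(g)),
      D = initialize(cfg, D0 = as.integer(g) %/% 2L,
                     D1 = as.integer(g) - as.integer(g) %/% 2L),
      M = initialize(cfg, M = as.integer(g)),
      N = initialize(cfg, N = as.integer(g)),
      sigma = initialize(cfg, sigma = as.numeric(g)),
      noise_family = initialize(cfg, noiseFamily = as.character(g)))
    if (verbose) message(sprintf("sweep %s = %s ...", axis, g))
    est <- estimateError(cg)
    est$axis <- axis
    est$value <- g
    repl[[as.character(g)]] <- attr(est, "replicates")
    out[[length(out) + 1L]] <- est
  }
  res <- do.call(rbind, out)
  attr(res, "replicates") <- repl
  res
}

#' Export classifier decisions as JSON records
#'
#' @param decisions a list of \linkS4class{ClassifierDecision} objects.
#' @param path output JSON path.
#' @param ids optional trajectory identifiers.
#' @param engine,seed optional provenance fields recorded per decision.
#' @export
writeDecisions <- function(decisions, path, ids = seq_along(decisions),
                           engine = NA_character_, seed = NA_integer_) {
  recs <- lapply(seq_along(decisions), function(i) {
    d <- decisions[[i]]
    list(id = ids[[i]], label = d@label, classifier = d@classifier,
         logScore0 = unname(d@logScores[1]), logScore1 = unname(d@logScores[2]),
         engine = engine, seed = seed)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
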