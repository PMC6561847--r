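test_that("posterior weighting follows Bayes rule over the model class", {
  sc <- toyScenario(sigma = 15)
  eng <- exactEngine()
  train <- trainingSet(simulateTrajectory(sc$true0, 4, nTraj = 2, seed = 1),
                       simulateTrajectory(sc$true1, 4, nTraj = 2, seed = 2))
  post <- fitPosterior(sc$uc, train, eng)
  expect_lt(abs(sum(post@posterior0) - 1), 1e-10)
  expect_lt(abs(sum(post@posterior1) - 1), 1e-10)

  # two-model closed form: posterior = logistic of the log-marginal gap
  d <- post@logMarginals0[1] - post@logMarginals0[2]
  expect_equal(post@posterior0[1], 1 / (1 + exp(-d)), tolerance = 1e-10)

  # identical models per class: posterior equals the prior
  mm <- sc$uc@models0[[1]]
  ucSame <- uncertaintyClass(list(mm, mm), list(sc$uc@models1[[1]], sc$uc@models1[[1]]),
                             prior0 = c(0.3, 0.7), prior1 = c(0.6, 0.4))
  postSame <- fitPosterior(ucSame, train, eng)
  expect_equal(postSame@posterior0, c(0.3, 0.7), tolerance = 1e-10)
  expect_equal(postSame@posterior1, c(0.6, 0.4), tolerance = 1e-10)

  # no training data: posterior degrades to the prior (OBC == IBR)
  post0 <- fitPosterior(sc$uc, trainingSet(), eng)
  expect_equal(post0@posterior0, sc$uc@prior0)
  test <- simulateTrajectory(sc$true0, 4, seed = 3)
  expect_equal(obcClassify(sc$uc, post0, test, eng)@label,
               ibrClassify(sc$uc, test, eng)@label)
})

test_that("posterior mass concentrates on the generating model with data", {
  sc <- toyScenario(sigma = 15)
  eng <- exactEngine()
  train <- trainingSet(simulateTrajectory(sc$true0, 6, nTraj = 32, seed = 4),
                       simulateTrajectory(sc$true1, 6, nTraj = 32, seed = 5))
  post <- fitPosterior(sc$uc, train, eng)
  expect_gt(post@posterior0[1], 0.95)
  expect_gt(post@posterior1[1], 0.95)
})

test_that("decision rules break ties toward class 0 and respect the prior", {
  sc <- toyScenario()
  eng <- exactEngine()
  test <- simulateTrajectory(sc$true0, 3, seed = 6)

  # an exact tie: both classes use the *same* models
  m <- sc$uc@models0[[1]]
  ucTie <- uncertaintyClass(list(m), list(m))
  postTie <- fitPosterior(ucTie, trainingSet(), eng)
  dec <- obcClassify(ucTie, postTie, test, eng)
  expect_identical(dec@label, 0L)
  expect_equal(dec@logScores[[1]], dec@logScores[[2]])

  # a degenerate class prior forces the decision
  uc1 <- uncertaintyClass(list(sc$uc@models0[[1]]), list(sc$uc@models1[[1]]),
                          p0 = 1)
  post1 <- fitPosterior(uc1, trainingSet(), eng)
  test1 <- simulateTrajectory(sc$true1, 3, seed = 7)   # class-1 data
  expect_identical(obcClassify(uc1, post1, test1, eng)@label, 0L)
})

test_that("all three rules collapse to the Bayes rule when M = 1", {
  sc <- toyScenario(M = 1)
  eng <- exactEngine()
  train <- trainingSet(simulateTrajectory(sc$true0, 3, nTraj = 2, seed = 8),
                       simulateTrajectory(sc$true1, 3, nTraj = 2, seed = 9))
  post <- fitPosterior(sc$uc, train, eng)
  for (s in 1:10) {
    test <- simulateTrajectory(if (s %% 2) sc$true0 else sc$true1, 3, seed = 20 + s)
    labs <- c(obcClassify(sc$uc, post, test, eng)@label,
              ibrClassify(sc$uc, test, eng)@label,
              pluginClassify(sc$uc, train, test, eng)@label)
    expect_equal(length(unique(labs)), 1L)
  }
})

test_that("plug-in selection is the training-likelihood argmax with stable ties", {
  sc <- toyScenario()
  eng <- exactEngine()
  # duplicated models guarantee exactly tied marginals -> lowest index wins;
  # decisions must equal those of the singleton class
  m0 <- sc$uc@models0[[1]]
  m1 <- sc$uc@models1[[1]]
  ucDup <- uncertaintyClass(list(m0, m0), list(m1, m1))
  uc1 <- uncertaintyClass(list(m0), list(m1))
  train <- trainingSet(simulateTrajectory(sc$true0, 3, nTraj = 2, seed = 10),
                       simulateTrajectory(sc$true1, 3, nTraj = 2, seed = 11))
  for (s in 1:6) {
    test <- simulateTrajectory(sc$true0, 3, seed = 30 + s)
    expect_identical(pluginClassify(ucDup, train, test, eng)@label,
                     pluginClassify(uc1, train, test, eng)@label)
  }
})

test_that("posterior weights are invariant to common log-marginal shifts", {
  lm <- c(-120.4, -118.9, -125.2)
  prior <- rep(1 / 3, 3)
  w1 <- scPOBDS:::.softmax(lm + log(prior))
  w2 <- scPOBDS:::.softmax((lm + 57.3) + log(prior))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("multicell densities match the two-component mixture formula", {
  # symmetric 1-gene chain: q = 0.5; hand-computed density at the midpoint
  m <- pobdsModel(parseRules("A = NOT A"), p = 0.1, lambda = 10, delta = 30,
                  sigma = 20)
  expect_equal(exp(multicellDensity(m, 25)), 0.01505687, tolerance = 1e-6)

  # point-mass steady state: a single Gaussian per gene
  mdet <- pobdsModel(parseRules("A = 1\nB = 0"), p = 1e-9, lambda = 10,
                     delta = 30, sigma = 20)
  y <- c(35, 12)
  expect_equal(multicellDensity(mdet, y),
               sum(dnorm(y, c(40, 10), 20, log = TRUE)), tolerance = 1e-6)

  # Monte-Carlo marginals agree with the exact ones
  m8 <- randomModel(8, 57)
  qEx <- scPOBDS:::.steadyMarginals(m8)
  pool <- steadyStatePool(m8, 2e4, seed = 12)
  expect_lt(max(abs(colMeans(pool) - qEx)), 0.01)

  # mixture mean per gene is lambda + delta * q
  mm <- pobdsModel(toyNet4(), p = 0.1, lambda = 10, delta = 30, sigma = 20)
  q <- scPOBDS:::.steadyMarginals(mm)
  smp <- sampleMulticell(mm, 4e4, seed = 13)
  expect_equal(unname(colMeans(smp)), unname(10 + 30 * q), tolerance = 0.02)
})

test_that("the multicell OBC degrades gracefully and uses its posterior", {
  sc <- toyScenario(sigma = 10)
  y <- sampleMulticell(sc$true0, 1, seed = 14)[1, ]
  # M = 1 reduces to a mixture likelihood-ratio rule
  uc1 <- uncertaintyClass(list(sc$uc@models0[[1]]), list(sc$uc@models1[[1]]))
  d1 <- multicellObc(uc1, NULL, NULL, y)
  s0 <- log(0.5) + multicellDensity(sc$uc@models0[[1]], y)
  s1 <- log(0.5) + multicellDensity(sc$uc@models1[[1]], y)
  expect_identical(d1@label, if (s0 >= s1) 0L else 1L)
  # no training: posterior = prior; decisions well-defined
  expect_s4_class(multicellObc(sc$uc, NULL, NULL, y), "ClassifierDecision")
})

test_that("multicell classification error grows with observation noise", {
  errs <- vapply(c(5, 12, 20, 30, 40), function(sg) {
    sc <- toyScenarioMC(sigma = sg)
    tr0 <- sampleMulticell(sc$true0, 12, seed = 15)
    tr1 <- sampleMulticell(sc$true1, 12, seed = 16)
    te0 <- sampleMulticell(sc$true0, 150, seed = 17)
    te1 <- sampleMulticell(sc$true1, 150, seed = 18)
    labs <- c(vapply(seq_len(nrow(te0)), function(i)
                multicellObc(sc$uc, tr0, tr1, te0[i, ])@label, integer(1)),
              vapply(seq_len(nrow(te1)), function(i)
                multicellObc(sc$uc, tr0, tr1, te1[i, ])@label, integer(1)))
    mean(labs != rep(c(0L, 1L), c(nrow(te0), nrow(te1))))
  }, numeric(1))
  expect_lt(errs[1], 0.1)              # well-separated regime
  expect_true(all(diff(errs) >= 0) || cor(seq_along(errs), errs) > 0.9)
  expect_gt(errs[5], errs[1])
})

test_that("decision records export as JSON", {
  sc <- toyScenario()
  eng <- exactEngine()
  post <- fitPosterior(sc$uc, trainingSet(), eng)
  decs <- lapply(1:3, function(s)
    obcClassify(sc$uc, post, simulateTrajectory(sc$true0, 3, seed = 40 + s), eng))
  f <- tempfile(fileext = ".json")
  writeDecisions(decs, f, engine = "exact", seed = 1)
  rec <- jsonlite::read_json(f)
  expect_length(rec, 3)
  expect_true(all(vapply(rec, function(r) r$label %in% c(0, 1), logical(1))))
})
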