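test_that("model construction enforces the noise invariants", {
  net <- toyNet3()
  expect_error(pobdsModel(net, p = 0.5), "0 < p < 0.5")
  expect_error(pobdsModel(net, p = -0.1), "0 < p < 0.5")
  expect_error(pobdsModel(net, p = 0.1, sigma = 0), "sigma")
  # NB needs overdispersion: variance must exceed the largest mean
  expect_error(pobdsModel(net, p = 0.1, lambda = 10, delta = 30, sigma = 5,
                          noiseFamily = "negative_binomial"), "overdispersion")
  expect_s4_class(pobdsModel(net, p = 0.1, lambda = 10, delta = 30, sigma = 25,
                             noiseFamily = "negative_binomial"), "PobdsModel")
})

test_that("state transitions reduce to the network function as p -> 0", {
  m <- pobdsModel(toyNet3(), p = 1e-12)
  x <- c(1, 0, 1)
  fx <- evaluateState(m@net, x)
  set.seed(1)
  for (i in 1:200) expect_identical(stepState(m, x), fx)
})

test_that("per-step flip counts follow Binomial(n, p)", {
  net <- randomNet(8, 4)
  m <- pobdsModel(net, p = 0.2)
  x <- indexToState(17, 8)[1, ]
  fx <- unname(evaluateState(net, x))
  set.seed(7)
  flips <- replicate(4000, sum(stepState(m, x) != fx))
  expect_lt(abs(mean(flips) - 8 * 0.2), 4 * sqrt(8 * 0.2 * 0.8 / 4000))
  cnt <- tabulate(flips + 1L, nbins = 9L)
  pr <- dbinom(0:8, 8, 0.2)
  keep <- pr > 5e-4
  suppressWarnings(ct <- chisq.test(cnt[keep], p = pr[keep] / sum(pr[keep])))
  expect_gt(ct$p.value, 1e-3)
})

test_that("observation sampling matches the stated families", {
  net <- parseRules("A = A")
  mg <- pobdsModel(net, p = 0.1, lambda = 10, delta = 30, sigma = 20)
  set.seed(2)
  y <- replicate(20000, sampleObservation(mg, 1))
  expect_lt(abs(mean(y) - 40), 4 * 20 / sqrt(20000))
  expect_lt(abs(sd(y) - 20), 1)

  mp <- pobdsModel(net, p = 0.1, lambda = 10, delta = 30,
                   noiseFamily = "poisson")
  set.seed(3)
  y <- replicate(20000, sampleObservation(mp, 0))
  expect_lt(abs(mean(y) - 10), 0.2)
  expect_lt(abs(var(y) / mean(y) - 1), 0.1)   # equidispersion

  mnb <- pobdsModel(net, p = 0.1, lambda = 10, delta = 30, sigma = 25,
                    noiseFamily = "negative_binomial")
  set.seed(4)
  y <- replicate(20000, sampleObservation(mnb, 1))
  expect_lt(abs(mean(y) - 40), 4 * 25 / sqrt(20000))
  expect_lt(abs(sd(y) - 25), 1.5)

  # degenerate noise limit
  m0 <- pobdsModel(net, p = 0.1, lambda = 10, delta = 30, sigma = 1e-12)
  expect_equal(unname(sampleObservation(m0, 1)), 40, tolerance = 1e-6)
})

test_that("trajectory simulation is seeded and consistent with the chain law", {
  m <- pobdsModel(toyNet3(), p = 0.05, sigma = 20)
  t1 <- simulateTrajectory(m, T = 1, seed = 5)
  expect_equal(nrow(t1@y), 1L)
  ta <- simulateTrajectory(m, T = 6, seed = 9)
  tb <- simulateTrajectory(m, T = 6, seed = 9)
  expect_identical(ta@y, tb@y)
  expect_identical(ta@x, tb@x)

  # ergodic theorem: long-run state-visit frequencies approach the exact
  # stationary law
  net <- randomNet(6, 21)
  m6 <- pobdsModel(net, p = 0.05, sigma = 20, modelId = "erg")
  tr <- simulateTrajectory(m6, T = 1e5, seed = 33)
  freq <- tabulate(stateToIndex(tr@x), nbins = 2^6) / 1e5
  pi <- as.numeric(steadyState(m6, method = "exact"))
  expect_lt(0.5 * sum(abs(freq - pi)), 0.05)
})

test_that("transition matrices match hand-computed cases", {
  id1 <- pobdsModel(parseRules("A = A"), p = 0.1)
  expect_equal(transitionMatrix(id1), matrix(c(0.9, 0.1, 0.1, 0.9), 2),
               tolerance = 1e-12)

  id2 <- pobdsModel(parseRules("A = A\nB = B"), p = 0.1)
  M2 <- transitionMatrix(id2)
  expect_equal(diag(M2), rep(0.81, 4), tolerance = 1e-12)
  expect_equal(M2[2, 1], 0.09, tolerance = 1e-12)
  expect_equal(M2[4, 1], 0.01, tolerance = 1e-12)

  # near-maximal noise flattens the kernel toward uniform
  mh <- pobdsModel(toyNet3(), p = 0.499)
  expect_lt(max(abs(transitionMatrix(mh) - 1 / 8)), 1e-3)
})

test_that("transition matrix columns are stochastic and positive", {
  for (seed in c(1, 6)) {
    m <- randomModel(5, seed)
    M <- transitionMatrix(m)
    expect_lt(max(abs(colSums(M) - 1)), 1e-12)
    expect_true(all(M > 0))
  }
})

test_that("frozen genes restrict transitions to the stuck subspace", {
  net <- freezeGenes(toyNet3(), C = 0)
  m <- pobdsModel(net, p = 0.1)
  M <- transitionMatrix(m)
  expect_lt(max(abs(colSums(M) - 1)), 1e-12)
  S <- stateMatrix(3)
  expect_true(all(M[S[, 3] == 1, ] == 0))
  # free-gene exponent: from any state, staying put on the free genes has
  # probability (1-p)^2 when f is the identity there
  tr <- simulateTrajectory(m, T = 50, seed = 2)
  expect_true(all(tr@x[, "C"] == 0L))
})

test_that("update diagonal matches the Gaussian density formula", {
  m <- pobdsModel(parseRules("A = 0"), p = 0.1, lambda = 10, delta = 30, sigma = 20)
  d <- updateDiagonal(m, 40)
  expect_equal(d[2], 0.0199471, tolerance = 1e-6)
  expect_equal(d[1], 0.00647588, tolerance = 1e-6)
  expect_true(all(d > 0))

  # density peaks at the state whose mean equals the observation
  m3 <- randomModel(3, 8)
  S <- stateMatrix(3)
  for (i in c(1, 4, 8)) {
    y <- m3@lambda + m3@delta * S[i, ]
    expect_equal(which.max(updateDiagonal(m3, y)), i)
  }

  # doubling sigma flattens likelihood ratios toward 1
  mA <- pobdsModel(parseRules("A = 0"), p = 0.1, lambda = 10, delta = 30, sigma = 20)
  mB <- pobdsModel(parseRules("A = 0"), p = 0.1, lambda = 10, delta = 30, sigma = 40)
  rA <- updateDiagonal(mA, 10)
  rB <- updateDiagonal(mB, 10)
  expect_gt(rB[2] / rB[1], rA[2] / rA[1])
  expect_lt(rB[2] / rB[1], 1)

  mp <- pobdsModel(toyNet3(), p = 0.1, noiseFamily = "poisson", sigma = 20)
  expect_error(updateDiagonal(mp, c(1, 2, 3)), class = "pobdsCapabilityError")
})

test_that("update diagonal is invariant under consistent gene permutation", {
  m <- randomModel(4, 12)
  y <- m@lambda + c(0, 30, 0, 15)
  d <- updateDiagonal(m, y)
  perm <- c(3, 1, 4, 2)
  netP <- parseRules(paste0("h", 1:4, " = h", 1:4))   # rules irrelevant to d
  mP <- pobdsModel(netP, p = m@p, lambda = m@lambda[perm],
                   delta = m@delta[perm], sigma = m@sigma)
  dP <- updateDiagonal(mP, y[perm])
  # map state indices through the bit permutation and compare
  S <- stateMatrix(4)
  iP <- stateToIndex(S[, perm])
  expect_equal(unname(dP[iP]), unname(d), tolerance = 1e-12)
})

test_that("steady state solves the stationarity equation", {
  m1 <- pobdsModel(parseRules("A = 0"), p = 0.1)
  expect_equal(as.numeric(steadyState(m1)), c(0.9, 0.1), tolerance = 1e-9)

  mh <- pobdsModel(toyNet3(), p = 0.499)
  expect_lt(max(abs(as.numeric(steadyState(mh)) - 1 / 8)), 1e-3)

  for (seed in c(2, 14)) {
    m <- randomModel(6, seed)
    pi <- as.numeric(steadyState(m))
    M <- transitionMatrix(m)
    expect_lt(sum(abs(M %*% pi - pi)), 1e-10)
    expect_true(all(pi > 0))
    # Monte-Carlo agrees with the exact stationary vector
    piMC <- as.numeric(steadyState(m, method = "monte_carlo", nSteps = 1e5,
                                   seed = 99))
    expect_lt(0.5 * sum(abs(pi - piMC)), 0.02)
  }
})

test_that("trajectory CSV round-trips exactly", {
  m <- pobdsModel(toyNet3(), p = 0.1, sigma = 20)
  tr <- simulateTrajectory(m, T = 5, seed = 3)
  fy <- tempfile(fileext = ".csv")
  fx <- tempfile(fileext = ".csv")
  writeTrajectory(tr, fy, statesPath = fx)
  back <- readTrajectory(fy, statesPath = fx)
  expect_identical(unname(back@y), unname(tr@y))
  expect_identical(unname(back@x), unname(tr@x))
  expect_equal(colnames(back@y), geneNames(m))
})

test_that("exact machinery refuses networks beyond the matrix guard", {
  big <- pobdsModel(tlglNetwork("true", "healthy"), p = 0.05, sigma = 20)
  expect_error(transitionMatrix(big), class = "pobdsCapabilityError")
  expect_error(steadyState(big), class = "pobdsCapabilityError")
  expect_error(updateDiagonal(big, rep(10, 18)), class = "pobdsCapabilityError")
})
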