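test_that("particle initialization draws from the steady state", {
  m <- randomModel(6, 42)
  ens <- initParticles(m, 1e5, seed = 1)
  freq <- tabulate(stateToIndex(ens@states), nbins = 2^6) / 1e5
  pi <- as.numeric(steadyState(m))
  expect_lt(0.5 * sum(abs(freq - pi)), 0.02)
  expect_equal(ens@weights, rep(1e-5, 1e5))

  e1 <- initParticles(m, 1, seed = 2)
  expect_equal(nrow(e1@states), 1L)
  expect_equal(e1@weights, 1)

  ea <- initParticles(m, 50, seed = 3)
  eb <- initParticles(m, 50, seed = 3)
  expect_identical(ea@states, eb@states)

  # Monte-Carlo pool route for a large network
  big <- pobdsModel(tlglNetwork("true", "healthy"), p = 0.05, sigma = 20)
  pool <- steadyStatePool(big, 2000, seed = 4)
  ebig <- initParticles(big, 500, ssPool = pool, seed = 5)
  expect_equal(dim(ebig@states), c(500L, 18L))
})

test_that("one APF step matches its defining limits", {
  m <- pobdsModel(toyNet3(), p = 0.1, lambda = 10, delta = 30, sigma = 1e6)
  ens <- initParticles(m, 400, seed = 6)
  # flat likelihood: second-stage weights ~ 1, aux probs ~ incoming weights
  st <- apfStep(ens, m, c(20, 20, 20), seed = 7)
  expect_lt(diff(range(st$ensemble@weights)) / mean(st$ensemble@weights), 1e-6)
  expect_lt(diff(range(st$ensemble@auxProbs)), 1e-9)

  # near-deterministic dynamics: propagated particles equal their modes,
  # so every density ratio is exactly 1
  md <- pobdsModel(toyNet3(), p = 1e-9, lambda = 10, delta = 30, sigma = 20)
  ensd <- initParticles(md, 400, ssPool = stateMatrix(3), seed = 8)
  std <- apfStep(ensd, md, c(40, 10, 10), seed = 9)
  expect_equal(std$ensemble@weights, rep(1 / 400, 400))
})

test_that("the APF increment converges to the exact filter value", {
  # the 1-gene worked example: increment -> -4.8506 for y = 40 from the
  # steady-state prior [0.9, 0.1]
  m <- pobdsModel(parseRules("A = 0"), p = 0.1, lambda = 10, delta = 30, sigma = 20)
  set.seed(10)
  incs <- replicate(30, {
    ens <- initParticles(m, 20000)
    apfStep(ens, m, 40)$logIncrement
  })
  expect_equal(mean(incs), -4.8506, tolerance = 2e-3)
})

test_that("particle log-likelihoods are consistent and reproducible", {
  m <- randomModel(3, 77)
  tr <- simulateTrajectory(m, T = 3, seed = 11)
  ex <- exactLogLik(m, tr)
  est <- vapply(1:60, function(i) apfLogLik(m, tr, N = 5000, seed = i), numeric(1))
  expect_lt(abs(mean(est) - ex), 0.05)
  ests <- vapply(1:60, function(i) sirLogLik(m, tr, N = 5000, seed = i), numeric(1))
  expect_lt(abs(mean(ests) - ex), 0.05)
  expect_identical(apfLogLik(m, tr, N = 300, seed = 5),
                   apfLogLik(m, tr, N = 300, seed = 5))
  expect_identical(sirLogLik(m, tr, N = 300, seed = 5),
                   sirLogLik(m, tr, N = 300, seed = 5))
})

test_that("the likelihood estimator is unbiased in linear space", {
  m <- randomModel(2, 19)
  tr <- simulateTrajectory(m, T = 2, seed = 13)
  ex <- exactLogLik(m, tr)
  est <- vapply(1:600, function(i) apfLogLik(m, tr, N = 200, seed = i), numeric(1))
  lin <- exp(est - ex)   # exact value scaled to 1
  expect_lt(abs(mean(lin) - 1), 2 * sd(lin) / sqrt(length(lin)))
})

test_that("estimator spread shrinks roughly like 1/sqrt(N)", {
  m <- randomModel(3, 29)
  tr <- simulateTrajectory(m, T = 3, seed = 14)
  e1 <- vapply(1:200, function(i) apfLogLik(m, tr, N = 1000, seed = i), numeric(1))
  e4 <- vapply(1:200, function(i) apfLogLik(m, tr, N = 4000, seed = 1000 + i), numeric(1))
  expect_lt(sd(e4), 0.6 * sd(e1))
})

test_that("APF beats plain SIR variance at few particles and low noise", {
  net <- randomNet(6, 65)
  m <- pobdsModel(net, p = 0.01, lambda = 10, delta = 30, sigma = 25)
  trs <- simulateTrajectory(m, T = 4, nTraj = 6, seed = 15)
  va <- vs <- numeric(6)
  for (j in 1:6) {
    a <- vapply(1:100, function(i) apfLogLik(m, trs[[j]], N = 50, seed = 1000 * j + i), numeric(1))
    s <- vapply(1:100, function(i) sirLogLik(m, trs[[j]], N = 50, seed = 1000 * j + i), numeric(1))
    va[j] <- var(a)
    vs[j] <- var(s)
  }
  expect_lt(mean(va), mean(vs))
})

test_that("the particle engines scale to the 18-gene network", {
  m <- pobdsModel(tlglNetwork("true", "healthy"), p = 0.05, sigma = 20,
                  modelId = "big")
  pool <- steadyStatePool(m, 3000, seed = 16)
  tr <- simulateTrajectory(m, T = 7, ssPool = pool, seed = 17)
  ll <- apfLogLik(m, tr, N = 1000, ssPool = pool, seed = 18)
  expect_true(is.finite(ll))
  lls <- sirLogLik(m, tr, N = 1000, ssPool = pool, seed = 18)
  expect_true(is.finite(lls))
})

test_that("non-Gaussian observation families run through the particle path", {
  net <- toyNet3()
  trP <- simulateTrajectory(pobdsModel(net, p = 0.05, lambda = 10, delta = 30,
                                       noiseFamily = "poisson"), T = 4, seed = 19)
  mP <- pobdsModel(net, p = 0.05, lambda = 10, delta = 30, noiseFamily = "poisson")
  expect_true(is.finite(apfLogLik(mP, trP, N = 500, seed = 20)))
  mNB <- pobdsModel(net, p = 0.05, lambda = 10, delta = 30, sigma = 25,
                    noiseFamily = "negative_binomial")
  trNB <- simulateTrajectory(mNB, T = 4, seed = 21)
  expect_true(is.finite(apfLogLik(mNB, trNB, N = 500, seed = 22)))
})

test_that("systematic resampling is a consistent, lower-variance alternative", {
  m <- randomModel(3, 83)
  tr <- simulateTrajectory(m, T = 3, seed = 23)
  ex <- exactLogLik(m, tr)
  est <- vapply(1:60, function(i)
    apfLogLik(m, tr, N = 4000, resampling = "systematic", seed = i), numeric(1))
  expect_lt(abs(mean(est) - ex), 0.05)
  expect_identical(apfLogLik(m, tr, N = 300, resampling = "systematic", seed = 4),
                   apfLogLik(m, tr, N = 300, resampling = "systematic", seed = 4))
  # the two schemes draw differently but estimate the same quantity
  eM <- vapply(1:60, function(i) apfLogLik(m, tr, N = 2000, seed = i), numeric(1))
  eS <- vapply(1:60, function(i)
    apfLogLik(m, tr, N = 2000, resampling = "systematic", seed = i), numeric(1))
  expect_lt(abs(mean(eM) - mean(eS)), 0.1)
})
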