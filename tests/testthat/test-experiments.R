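# Small toy-scenario configurations keep these tests fast; the full-size
# study design is exercised in test-acceptance.R.

toyCfg <- function(..., sigma = 10, nReps = 4L, nTestPerClass = 40L) {
  sc <- toyScenario(sigma = sigma)
  scenarioConfig(engine = "exact", sigma = sigma, nReps = nReps,
                 nTestPerClass = nTestPerClass, seed = 7,
                 customUC = sc$uc, customTrue = list(sc$true0, sc$true1), ...)
}

test_that("scenario configs validate and read from YAML", {
  expect_error(scenarioConfig(nReps = 0), "nReps")
  expect_error(scenarioConfig(T = 0), "T must")
  expect_error(scenarioConfig(engine = "magic"))
  cfg <- scenarioConfig(T = 5, p = 0.1, D = 6, N = 200, nReps = 3)
  expect_equal(cfg@D0, 3L)
  expect_equal(cfg@D1, 3L)

  f <- tempfile(fileext = ".yaml")
  writeLines(c("T: 4", "p: 0.1", "sigma: 25", "D: 4", "particles: 500",
               "engine: apf", "nReps: 2", "nTestPerClass: 10", "seed: 3"), f)
  cfg2 <- readScenarioConfig(f)
  expect_equal(cfg2@T, 4L)
  expect_equal(cfg2@N, 500L)
  expect_equal(cfg2@engine, "apf")
})

test_that("scenario data is balanced, split equally and seed-reproducible", {
  cfg <- toyCfg(T = 3, D = 4, nTestPerClass = 15L)
  d1 <- generateScenarioData(cfg, 1)
  expect_length(d1$train@class0, 2L)
  expect_length(d1$train@class1, 2L)
  expect_length(d1$test0, 15L)
  expect_length(d1$test1, 15L)
  d2 <- generateScenarioData(cfg, 1)
  expect_identical(d1$train@class0[[1]]@y, d2$train@class0[[1]]@y)
  expect_identical(d1$test1[[7]]@y, d2$test1[[7]]@y)
  d3 <- generateScenarioData(cfg, 2)
  expect_false(identical(d1$test0[[1]]@y, d3$test0[[1]]@y))
})

test_that("generated latent states match the steady-state marginals", {
  cfg <- toyCfg(T = 2, nTestPerClass = 2500L)
  d <- generateScenarioData(cfg, 1)
  x1 <- do.call(rbind, lapply(d$test0, function(t) t@x[1, , drop = FALSE]))
  freq <- tabulate(stateToIndex(x1), nbins = 2^4) / nrow(x1)
  piM <- as.numeric(transitionMatrix(cfg@customTrue[[1]]) %*%
                    as.numeric(steadyState(cfg@customTrue[[1]])))
  expect_lt(0.5 * sum(abs(freq - piM)), 0.05)
})

test_that("identical classes give chance-level error", {
  sc <- toyScenario(sigma = 10)
  uc <- uncertaintyClass(list(sc$true0), list(sc$true0))
  cfg <- scenarioConfig(engine = "exact", T = 3, nReps = 4, nTestPerClass = 150,
                        seed = 11, customUC = uc,
                        customTrue = list(sc$true0, sc$true0))
  est <- estimateError(cfg)
  se <- sqrt(0.25 / (4 * 300))
  expect_lt(abs(est$meanError[est$classifier == "obc"] - 0.5), 3 * se + 0.02)
})

test_that("a near-separable regime yields near-zero error", {
  cfg <- toyCfg(T = 8, sigma = 1, p = 0.05, nReps = 3, nTestPerClass = 100)
  est <- estimateError(cfg)
  expect_lt(est$meanError[est$classifier == "obc"], 0.02)
})

test_that("error estimation is deterministic and accounts for replicates", {
  cfg <- toyCfg(T = 3)
  e1 <- estimateError(cfg)
  e2 <- estimateError(cfg)
  expect_identical(e1$meanError, e2$meanError)
  expect_identical(attr(e1, "replicates"), attr(e2, "replicates"))
  expect_true(all(e1$nReps + e1$nFailed == cfg@nReps))
  expect_equal(sort(e1$classifier), sort(cfg@classifiers))
  expect_true(all(e1$meanError >= 0 & e1$meanError <= 1))
  expect_true(all(e1$sdError >= 0))
})

test_that("the particle engine reproduces the exact engine's error levels", {
  sc <- toyScenario(sigma = 10)
  base <- list(T = 4L, nReps = 6L, nTestPerClass = 60L)
  cfgE <- scenarioConfig(engine = "exact", T = 4, nReps = 6, nTestPerClass = 60,
                         seed = 5, customUC = sc$uc,
                         customTrue = list(sc$true0, sc$true1))
  cfgA <- scenarioConfig(engine = "apf", N = 4000, T = 4, nReps = 6,
                         nTestPerClass = 60, seed = 5, customUC = sc$uc,
                         customTrue = list(sc$true0, sc$true1))
  eE <- estimateError(cfgE)
  eA <- estimateError(cfgA)
  rE <- attr(eE, "replicates")[, "obc"]
  rA <- attr(eA, "replicates")[, "obc"]
  d <- rA - rE   # paired by shared data seeds
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 1e-9)
})

test_that("sweeps share seeds across the grid and report one row per point", {
  cfg <- toyCfg(T = 2, nReps = 3, nTestPerClass = 30)
  sw <- runSweep("T", c(2, 4), cfg, verbose = FALSE)
  expect_equal(nrow(sw), 2 * length(cfg@classifiers))
  expect_setequal(unique(sw$value), c(2, 4))
  repl <- attr(sw, "replicates")
  expect_length(repl, 2)
  # D sweep splits totals equally
  swD <- runSweep("D", c(2, 6), cfg, verbose = FALSE)
  expect_equal(nrow(swD), 2 * length(cfg@classifiers))
})

test_that("runTable2 assembles the full comparison grid", {
  sc <- toyScenario(sigma = 10)
  cfg <- scenarioConfig(engine = "exact", nReps = 2, nTestPerClass = 10,
                        seed = 3, customUC = sc$uc,
                        customTrue = list(sc$true0, sc$true1))
  tab <- runTable2(cfg, ps = 0.05, Ts = c(2L, 3L), verbose = FALSE)
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$T), c(2L, 3L))
  expect_setequal(unique(tab$classifier), c("obc", "ibr", "plugin"))
})

test_that("the multicell classifier plugs into the scenario runner", {
  cfg <- toyCfg(T = 3, nReps = 3, nTestPerClass = 50)
  cfg <- initialize(cfg, classifiers = c("obc", "multicell_obc"))
  est <- estimateError(cfg)
  expect_setequal(est$classifier, c("obc", "multicell_obc"))
  expect_true(all(is.finite(est$meanError)))
})
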