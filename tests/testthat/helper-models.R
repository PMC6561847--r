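# Small fixture networks and models, built in code.

toyNet3 <- function() {
  parseRules("A = NOT B\nB = A AND C\nC = NOT (A OR C)")
}

toyNet4 <- function() {
  parseRules(c("A = NOT B", "B = A AND C", "C = NOT (A OR D)", "D = C OR B"))
}

# a second, dynamically different 4-gene network (for two-class scenarios)
toyNet4b <- function() {
  parseRules(c("A = B OR D", "B = NOT A", "C = A AND NOT C", "D = NOT (B OR C)"))
}

# random Boolean network: each gene gets a rule combining 2-3 regulators
randomNet <- function(n, seed) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n))
    rules <- vapply(seq_len(n), function(j) {
      k <- sample(2:min(3, n), 1)
      regs <- sample(genes, k)
      lits <- ifelse(stats::runif(k) < 0.4, paste("NOT", regs), regs)
      op <- sample(c(" AND ", " OR "), 1)
      paste0(genes[j], " = ", paste(lits, collapse = op))
    }, character(1))
    parseRules(rules)
  })
}

randomModel <- function(n, seed) {
  net <- randomNet(n, seed)
  withr::with_seed(seed + 1L, {
    pobdsModel(net,
               p = stats::runif(1, 0.01, 0.3),
               lambda = stats::runif(n, 5, 15),
               delta = stats::runif(n, 20, 40),
               sigma = stats::runif(1, 10, 30),
               modelId = paste0("rand", seed))
  })
}

# a two-class toy scenario (distinct 4-gene networks) for classifier tests
toyScenario <- function(p = 0.05, sigma = 10, M = 2) {
  mk <- function(net, id) pobdsModel(net, p = p, lambda = 10, delta = 30,
                                     sigma = sigma, modelId = id)
  m0 <- list(mk(toyNet4(), "c0_true"), mk(randomNet(4, 71), "c0_alt"))[seq_len(M)]
  m1 <- list(mk(toyNet4b(), "c1_true"), mk(randomNet(4, 72), "c1_alt"))[seq_len(M)]
  list(uc = uncertaintyClass(m0, m1), true0 = m0[[1]], true1 = m1[[1]])
}

# a class pair with well-separated steady-state marginals (OR-coupled genes
# absorb near all-ON, AND-coupled near all-OFF) for multicell tests
toyScenarioMC <- function(sigma = 10, p = 0.05) {
  mk <- function(txt, id) pobdsModel(parseRules(txt), p = p, lambda = 10,
                                     delta = 30, sigma = sigma, modelId = id)
  m0 <- mk("A = A OR B\nB = B OR C\nC = C OR A\nD = NOT D", "mc0")
  m1 <- mk("A = A AND B\nB = B AND C\nC = C AND A\nD = NOT D", "mc1")
  list(uc = uncertaintyClass(list(m0), list(m1)), true0 = m0, true1 = m1)
}
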