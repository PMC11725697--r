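test_that("chains are bit-identical under the same seed", {
  sc <- suppressWarnings(presetStudy2(I = 40, J = 4, seed = 5))
  sim <- simulateDataset(sc)
  mc <- shortMcmc(seed = 9)
  a <- runChain(sc@graph, sim$data, mc, chainId = 2)
  b <- runChain(sc@graph, sim$data, mc, chainId = 2)
  expect_identical(a$draws, b$draws)
  c3 <- runChain(sc@graph, sim$data, mc, chainId = 3)
  expect_false(identical(a$draws, c3$draws))
})

test_that("adapted random-walk acceptance rates land in a usable band", {
  sc <- suppressWarnings(presetStudy2(I = 80, J = 4, seed = 21))
  sim <- simulateDataset(sc)
  ch <- runChain(sc@graph, sim$data,
                 mcmcConfig(nIterations = 2500, burnIn = 1200, thin = 1,
                            seed = 3),
                 chainId = 1)
  expect_true(all(ch$acceptRate > 0.1 & ch$acceptRate < 0.7))
})

test_that("with fully masked data the posterior reproduces the prior", {
  ## 24 sites, every occasion unsampled: no likelihood contribution. A
  ## Normal(0, 1) prior keeps the implied lambda well inside the truncated
  ## latent support, so the detailed-balance check is clean.
  y <- matrix(NA_integer_, 24, 3)
  dat <- oneSpeciesData(y, mask = matrix(FALSE, 24, 3))
  ## the truncation monitor fires occasionally here by design: with no data,
  ## the latent states wander the whole prior
  fit <- suppressWarnings(
    fitModel(oneSpeciesGraph(), dat,
             mcmcConfig(nChains = 2, nIterations = 8000, burnIn = 2000,
                        thin = 2, seed = 31),
             priors = list(sd = 1)))
  s <- posteriorSummary(fit)
  expect_true(all(abs(s$mean) < 0.25))
  expect_true(all(s$sd > 0.85 & s$sd < 1.15))
})

test_that("single-species Royle-Nichols reduction recovers its parameters", {
  g <- oneSpeciesGraph()
  truths <- c(D_state_int = log(1.5), D_det_int = qlogis(0.4))
  sc <- simulationScenario(studyDesign(200, 5, 1), g, truths, seed = 77)
  sim <- simulateDataset(sc)
  fit <- fitModel(g, sim$data,
                  mcmcConfig(nIterations = 3000, burnIn = 800, thin = 2,
                             seed = 13))
  s <- posteriorSummary(fit)
  expect_true(isConverged(fit))
  expect_true(all(s$lo95 <= truths & truths <= s$hi95))
})

test_that("a downstream absence with negative interaction shifts latent abundance upward", {
  ## if the subordinate is absent and gamma0 < 0, larger dominant N makes
  ## that absence more likely, so the conditional must put more mass on
  ## large N than the no-downstream conditional (stochastic dominance)
  g <- twoSpeciesGraph()
  dat <- tinyData(yD = matrix(c(1L, 1L), 1, 2), yS = matrix(0L, 1, 2))
  withS <- latentAbundancePmf(1, "D", c(D = 1, S = 0), tinyCoefs(-1), dat, g,
                              nMax = 25)
  without <- latentAbundancePmf(1, "D", c(D = 1, S = 0), tinyCoefs(0), dat, g,
                                nMax = 25)
  expect_true(all(cumsum(withS) <= cumsum(without) + 1e-12))
  expect_true(any(cumsum(withS) < cumsum(without) - 1e-6))
})

test_that("single-site update operations respect structural constraints", {
  g <- twoSpeciesGraph()
  dat <- tinyData(yD = matrix(c(1L, 1L), 1, 2), yS = matrix(c(1L, 0L), 1, 2))
  set.seed(1)
  for (k in 1:20)
    expect_gte(updateLatentAbundance(1, "D", c(D = 1, S = 1), tinyCoefs(),
                                     dat, g, nMax = 10), 1)
  expect_identical(updateLatentOccupancy(1, "S", c(D = 1, S = 1), tinyCoefs(),
                                         dat, g), 1L)
  datEmpty <- tinyData(yD = matrix(0L, 1, 2), yS = matrix(0L, 1, 2))
  ## psi = 0 forces z = 0
  coefs0 <- tinyCoefs(0); coefs0["S_state_int"] <- -40
  set.seed(2)
  expect_identical(updateLatentOccupancy(1, "S", c(D = 0, S = 0), coefs0,
                                         datEmpty, g), 0L)
})

test_that("fitModel reports diagnostics for every parameter and handles one chain", {
  sc <- suppressWarnings(presetStudy2(I = 40, J = 4, seed = 15))
  sim <- simulateDataset(sc)
  fit <- fitModel(sc@graph, sim$data, shortMcmc(nChains = 3, seed = 2))
  expect_identical(nrow(fit@rhat), nrow(parameterIndex(sc@graph)))
  expect_true(all(is.finite(fit@rhat$upper)))
  fit1 <- fitModel(sc@graph, sim$data, shortMcmc(nChains = 1, seed = 2))
  expect_true(is.na(isConverged(fit1)))
  expect_true(all(is.na(fit1@rhat$point)))
  expect_s4_class(fit1, "PosteriorResult")
})

test_that("the mcmc configuration enforces its invariants", {
  expect_error(mcmcConfig(nIterations = 500, burnIn = 200, thin = 5),
               "100 retained")
  cfg <- mcmcConfig(preset = "paper")
  expect_identical(cfg$nIterations, 50000L)
  expect_identical(cfg$burnIn, 5000L)
  expect_gte((cfg$nIterations - cfg$burnIn) / cfg$thin, 100)
})

test_that("posterior ranks of prior-drawn truths are uniform (calibration)", {
  ## simulation-based calibration, reduced scale: draw the truth from the
  ## prior, simulate, fit with that same prior, record the rank of the truth
  ## among the retained gamma0 draws; ranks must be uniform
  g <- twoSpeciesGraph()
  prior <- list(parameters = list(
    D_state_int = list(mean = 0, sd = 0.5),
    D_det_int = list(mean = 0, sd = 0.5),
    S_state_int = list(mean = 0, sd = 0.5),
    S_state_gamma0_D = list(mean = -1, sd = 0.5),
    S_det_int = list(mean = 0, sd = 0.5)))
  ranks <- vapply(1:60, function(k) {
    set.seed(9000 + k)
    tv <- c(D_state_int = rnorm(1, 0, 0.5), D_det_int = rnorm(1, 0, 0.5),
            S_state_int = rnorm(1, 0, 0.5),
            S_state_gamma0_D = rnorm(1, -1, 0.5),
            S_det_int = rnorm(1, 0, 0.5))
    sck <- simulationScenario(studyDesign(50, 4, 1), g, tv, seed = 9000 + k)
    simk <- simulateDataset(sck)
    fk <- suppressWarnings(fitModel(g, simk$data,
      mcmcConfig(nChains = 1, nIterations = 1400, burnIn = 400, thin = 10,
                 seed = 40 + k),
      priors = prior))
    d <- draws(fk, combine = TRUE)[, "S_state_gamma0_D"]
    sum(d < tv[["S_state_gamma0_D"]])
  }, 0)
  h <- tabulate(cut(ranks / 101, breaks = seq(0, 1, by = 0.2),
                    include.lowest = TRUE, labels = FALSE), nbins = 5)
  expect_gt(chisq.test(h)$p.value, 0.01)
})
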