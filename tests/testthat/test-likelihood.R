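test_that("Royle-Nichols detection probability is exact and monotone", {
  expect_identical(rnDetectionProb(0.3, 0), 0)
  expect_identical(rnDetectionProb(0.5, 1), 0.5)
  expect_equal(rnDetectionProb(0.3, 2), 0.51)
  expect_error(rnDetectionProb(1.2, 1), "r must lie")
  expect_error(rnDetectionProb(0.5, -1), "non-negative")
  ## nondecreasing in N and in r over a grid
  for (r in c(0, 0.17, 0.5, 0.93, 1)) {
    p <- rnDetectionProb(r, 0:20)
    expect_true(all(diff(p) >= 0))
  }
  rs <- seq(0, 1, by = 0.05)
  for (N in c(0, 1, 3, 10))
    expect_true(all(diff(rnDetectionProb(rs, N)) >= 0))
})

test_that("binomial observation log-density matches the closed form and normalizes", {
  expect_equal(binomObsLoglik(0, 1, 0.3), log(0.7))
  expect_equal(binomObsLoglik(2, 7, 0.51),
               lchoose(7, 2) + 2 * log(0.51) + 5 * log(0.49))
  ## cross-check against an independent pmf routine
  expect_equal(binomObsLoglik(2, 7, 0.51), dbinom(2, 7, 0.51, log = TRUE))
  expect_identical(binomObsLoglik(3, 7, 0), -Inf)
  expect_identical(binomObsLoglik(0, 7, 0), 0)
  expect_error(binomObsLoglik(9, 7, 0.5), "0..K")
  for (K in c(1, 4, 7, 10))
    for (p in c(0, 0.25, 0.51, 1))
      expect_equal(sum(exp(binomObsLoglik(0:K, K, p))), 1)
})

test_that("Bernoulli observation log-density encodes no-false-positives", {
  expect_identical(bernoulliObsLoglik(1, 0.5, 0), -Inf)
  expect_identical(bernoulliObsLoglik(0, 0.5, 0), 0)
  expect_equal(bernoulliObsLoglik(1, 0.5, 1), log(0.5))
  expect_equal(bernoulliObsLoglik(0, 0.3, 1), log(0.7))
  expect_error(bernoulliObsLoglik(2, 0.5, 1), "binary")
})

test_that("linear predictor assembles interaction terms on the link scale", {
  g <- twoSpeciesGraph()
  coefs <- tinyCoefs(gamma0 = -1)
  eta <- linearPredictor(g, "S", "state", numeric(0), coefs, c(D = 2, S = 0))
  expect_equal(eta, -2)
  expect_equal(plogis(eta), 1 / (1 + exp(2)))

  gm <- buildModelGraph(twoSpeciesConfig(modifier = TRUE))
  coefsM <- c(D_state_int = 0, D_det_int = 0, S_state_int = 0,
              S_state_gamma0_D = -1, S_state_gamma1_D_x_x2 = 1,
              S_det_int = 0)
  expect_equal(linearPredictor(gm, "S", "state", c(x2 = 1), coefsM,
                               c(D = 2, S = 0)), -2 + 2)

  ## occupancy-mediated variant: the indicator replaces N
  go <- asOccupancyMediated(g)
  expect_equal(linearPredictor(go, "S", "state", numeric(0), coefs,
                               c(D = 3, S = 0)), -1)
  expect_error(linearPredictor(g, "S", "state", numeric(0), coefs,
                               c(S = 0)), "upstream state")
})

test_that("site joint log-density is the sum of its parts and honors masks", {
  g <- twoSpeciesGraph()
  dat <- tinyData(yD = matrix(c(1L, 0L), 1, 2), yS = matrix(c(0L, 1L), 1, 2))
  coefs <- tinyCoefs()
  states <- c(D = 2, S = 1)
  direct <- dpois(2, exp(0), log = TRUE) +
    sum(binomObsLoglik(c(1, 0), 1, rnDetectionProb(plogis(0), 2))) +
    {psi <- plogis(0 + -1 * 2); log(psi)} +
    sum(bernoulliObsLoglik(c(0, 1), plogis(0), 1))
  expect_equal(siteJointLoglik(1, states, coefs, dat, g), direct)

  ## one species, N = 0, all y = 0: only the Poisson term remains
  g1 <- oneSpeciesGraph()
  d1 <- oneSpeciesData(matrix(0L, 1, 2))
  expect_equal(siteJointLoglik(1, c(D = 0), c(D_state_int = log(2),
                                              D_det_int = 0), d1, g1),
               dpois(0, 2, log = TRUE))

  ## a masked occasion contributes exactly zero
  mask <- matrix(c(TRUE, FALSE), 1, 2)
  dMask <- tinyData(yD = matrix(c(1L, NA), 1, 2),
                    yS = matrix(c(0L, NA), 1, 2), mask = mask)
  dShort <- tinyData(yD = matrix(1L, 1, 1), yS = matrix(0L, 1, 1),
                     nOccasions = 1)
  expect_equal(siteJointLoglik(1, states, coefs, dMask, g),
               siteJointLoglik(1, states, coefs, dShort, g))
})

test_that("with gamma = 0 the subordinate marginal is the MacKenzie occupancy likelihood", {
  g <- oneOccupancyGraph()
  psi <- 0.62; p <- 0.37
  coefs <- c(S_state_int = qlogis(psi), S_det_int = qlogis(p))
  for (y in list(c(0L, 0L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L))) {
    dat <- new("DetectionData", y = list(S = matrix(y, 1, 3)),
               design = studyDesign(1, 3, 1),
               covariates = data.frame(row.names = 1), siteIds = "1")
    marg <- log(sum(exp(vapply(0:1, function(z)
      siteJointLoglik(1, c(S = z), coefs, dat, g), 0))))
    closed <- log(psi * prod(p^y * (1 - p)^(1 - y)) +
                    (1 - psi) * as.numeric(all(y == 0)))
    expect_equal(marg, closed)
  }
})

test_that("a 0/1-truncated R-N site likelihood equals an occupancy likelihood with psi = 1 - exp(-lambda)", {
  lambda <- 0.8; r <- 0.44
  psi <- 1 - exp(-lambda)
  for (y in list(c(0L, 0L), c(1L, 0L), c(1L, 1L))) {
    ## N restricted to {0, 1} with the Poisson masses renormalised to
    ## {P(N=0), P(N>0)}
    rn <- exp(-lambda) * prod(exp(binomObsLoglik(y, 1, rnDetectionProb(r, 0)))) +
      (1 - exp(-lambda)) * prod(exp(binomObsLoglik(y, 1, rnDetectionProb(r, 1))))
    occ <- psi * prod(r^y * (1 - r)^(1 - y)) +
      (1 - psi) * as.numeric(all(y == 0))
    expect_equal(rn, occ)
  }
})

test_that("brute-force latent conditionals are proper and respect structural zeros", {
  g <- twoSpeciesGraph()
  dat <- tinyData(yD = matrix(c(1L, 0L), 1, 2), yS = matrix(0L, 1, 2))
  pmf <- latentAbundancePmf(1, "D", c(D = 1, S = 0), tinyCoefs(), dat, g,
                            nMax = 20)
  expect_equal(sum(pmf), 1)
  expect_identical(pmf[1], 0)  # a detection forces N >= 1
  pz <- latentOccupancyProb(1, "S", c(D = 1, S = 0), tinyCoefs(0), dat, g)
  expect_equal(pz, 0.125 / 0.625)  # psi = 0.5, p = 0.5, J = 2, no detections
})
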