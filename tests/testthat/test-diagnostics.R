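test_that("Gelman-Rubin diagnoses stationarity and divergence", {
  set.seed(42)
  same <- list(rnorm(2000), rnorm(2000), rnorm(2000))
  gd <- gelmanRubin(same)
  expect_lt(abs(gd$point - 1), 0.01)
  apart <- list(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(gelmanRubin(apart)$point, 1.1)
  ## rank-free: permuting draws within a chain leaves R-hat unchanged
  perm <- lapply(apart, sample)
  expect_equal(gelmanRubin(perm)$point, gelmanRubin(apart)$point)
  ## single chain: unavailable
  expect_true(is.na(gelmanRubin(list(rnorm(500)))$point))
  ## matrix input: one entry per column
  m <- cbind(a = rnorm(500), b = rnorm(500))
  expect_length(gelmanRubin(list(m, m + 0))$point, 2L)
})

test_that("posterior mode follows the dominant mass", {
  expect_identical(posteriorMode(rep(3.7, 200)), 3.7)
  set.seed(7)
  expect_lt(abs(posteriorMode(rnorm(1e5))), 0.1)
  bim <- c(rnorm(7000, -2, 0.1), rnorm(3000, 2, 0.1))
  expect_lt(abs(posteriorMode(bim) - (-2)), 0.2)
})

test_that("equal-tailed credible intervals are empirical quantiles", {
  expect_identical(equalTailedCri(rep(1.5, 150)), c(1.5, 1.5))
  set.seed(8)
  u <- runif(1e5)
  ci <- equalTailedCri(u)
  expect_lt(abs(ci[1] - 0.025), 0.005)
  expect_lt(abs(ci[2] - 0.975), 0.005)
  expect_equal(equalTailedCri(-u), -rev(equalTailedCri(u)))
})

test_that("effective size is near n for independent draws", {
  set.seed(9)
  ess <- effectiveSizeDraws(list(matrix(rnorm(4000), ncol = 2)))
  expect_true(all(ess > 1000))
})

test_that("the Pearson discrepancy is zero (p = 1) when data equal their expectation", {
  ## constant posterior: theta fixed, latent fixed at N = 1; with K = 2 and
  ## r = 0.5 the expected count is exactly 1, so y = 1 gives T(y) = 0
  g <- oneSpeciesGraph()
  y <- matrix(1L, 4, 2)
  dat <- oneSpeciesData(y, K = 2L)
  theta <- c(D_state_int = 0, D_det_int = 0)
  drawsM <- matrix(rep(theta, each = 60), 60,
                   dimnames = list(NULL, names(theta)))
  latM <- matrix(1L, 60, 4)
  fit <- new("PosteriorResult", draws = list(drawsM),
             parameters = names(theta),
             summaries = data.frame(), rhat = data.frame(), converged = NA,
             ppc = numeric(0), latent = list(latM),
             mcmc = list(), graph = g)
  set.seed(11)
  expect_identical(ppcPearson(fit, dat, "D", nRep = 60), 1)
})

test_that("the convergence flag matches a manual recomputation from the chains", {
  sc <- suppressWarnings(presetStudy2(I = 50, J = 4, seed = 33))
  sim <- simulateDataset(sc)
  fit <- fitModel(sc@graph, sim$data,
                  mcmcConfig(nIterations = 1500, burnIn = 500, thin = 2,
                             seed = 4))
  manual <- gelmanRubin(draws(fit))
  expect_equal(fit@rhat$upper, manual$upper)
  expect_identical(isConverged(fit), all(manual$upper < 1.1))
})

test_that("summaries are invariant to chain order and stable under post-hoc thinning", {
  sc <- suppressWarnings(presetStudy2(I = 50, J = 4, seed = 34))
  sim <- simulateDataset(sc)
  fit <- fitModel(sc@graph, sim$data,
                  mcmcConfig(nIterations = 2100, burnIn = 600, thin = 1,
                             seed = 6))
  d <- draws(fit)
  all1 <- do.call(rbind, d)
  all2 <- do.call(rbind, rev(d))
  expect_equal(sort(apply(all1, 2, posteriorMode)),
               sort(apply(all2, 2, posteriorMode)))
  thin2 <- all1[seq(1, nrow(all1), by = 2), ]
  expect_lt(max(abs(colMeans(thin2) - colMeans(all1))), 0.1)
})
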