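test_that("study presets encode the published scenario constants", {
  s1 <- presetStudy1(0.5)
  expect_identical(nSites(s1@design), 600L)
  expect_identical(nOccasions(s1@design), 4L)
  expect_equal(plogis(s1@trueValues[["D_det_int"]]), 0.3)
  expect_equal(plogis(s1@trueValues[["S_det_int"]]), 0.5)
  expect_equal(s1@trueValues[["S_state_gamma0_D"]], -1)
  expect_equal(s1@trueValues[["S_state_gamma1_D"]], 0)
  expect_equal(s1@trueValues[["D_state_int"]], log(0.5))
  expect_warning(presetStudy1(3), "beyond the studied values")

  s2 <- presetStudy2(300, 4, varying = FALSE)
  expect_equal(plogis(s2@trueValues[["D_det_int"]]), 0.5)
  expect_equal(exp(s2@trueValues[["D_state_int"]]), 1)
  expect_false("S_state_gamma1_D_x_x2" %in% parameterIndex(s2)$name)
  s2v <- presetStudy2(1000, 10, varying = TRUE)
  expect_equal(s2v@trueValues[["S_state_gamma1_D_x_x2"]], 1)
  expect_identical(nrow(parameterIndex(s2v)),
                   nrow(parameterIndex(s2)) + 1L)

  s3 <- presetStudy3(0.05, 0.25)
  tv <- s3@trueValues
  expect_equal(tv[["I_state_gamma0_D"]], -1)
  expect_equal(tv[["S_state_gamma0_I"]], -1)
  expect_equal(tv[["S_state_gamma0_D"]], 1)
  expect_equal(plogis(tv[["I_det_int"]]), 0.5)  # fixed for any arguments
  expect_equal(plogis(tv[["D_det_int"]]), 0.05)
  expect_identical(topologicalOrder(s3@graph), c("D", "I", "S"))
})

test_that("solved intercepts hit the target mean occupancy", {
  ## the subordinate intercept is solved so the scenario-average occupancy
  ## equals the stated target; verify on large realized simulations
  for (spec in list(list(sc = presetStudy1(0.5, seed = 101), target = 0.75),
                    list(sc = presetStudy2(1000, 4, seed = 102), target = 0.5))) {
    sim <- simulateDataset(spec$sc)
    zbar <- mean(sim$truth$latent[, "S"])
    expect_lt(abs(zbar - spec$target), 0.05)
  }
})

test_that("simulation is deterministic given the seed and follows the state model", {
  sc <- presetStudy1(2, seed = 7L)
  a <- simulateDataset(sc)
  b <- simulateDataset(sc)
  expect_identical(a$data@y, b$data@y)
  expect_identical(a$truth$latent, b$truth$latent)
  ## Poisson mean check at lambda = 2, I = 600
  expect_lt(abs(mean(a$truth$latent[, "D"]) - 2), 3 * sqrt(2 / 600))
  ## r = 0 silences the dominant species regardless of N
  tv <- sc@trueValues; tv["D_det_int"] <- -40
  sc0 <- simulationScenario(sc@design, sc@graph, tv, seed = 8)
  expect_true(all(simulateDataset(sc0)$data@y$D == 0, na.rm = TRUE))
  ## an overwhelming negative interaction empties occupied-dominant sites
  tv2 <- sc@trueValues; tv2["S_state_gamma0_D"] <- -10
  simStrong <- simulateDataset(simulationScenario(sc@design, sc@graph, tv2,
                                                  seed = 9))
  occ <- simStrong$truth$latent[, "S"][simStrong$truth$latent[, "D"] >= 1]
  expect_lt(mean(occ), 0.02)
})

test_that("three-species simulation expresses the negative intermediate-subordinate link", {
  sim <- simulateDataset(presetStudy3(0.5, 0.5, seed = 11))
  lat <- sim$truth$latent
  detS <- rowMeans(sim$data@y$S) > 0
  ## holding the dominant count fixed at its most common values, subordinate
  ## detection frequency decreases with realized intermediate abundance
  for (nd in 0:1) {
    sel <- lat[, "D"] == nd
    lo <- detS[sel & lat[, "I"] == 0]
    hi <- detS[sel & lat[, "I"] >= 2]
    if (length(lo) > 20 && length(hi) > 20)
      expect_gt(mean(lo), mean(hi))
  }
})

test_that("the synthetic case-study scenario has the stated shape", {
  sc <- presetCaseStudySynthetic(seed = 3)
  d <- sc@design
  expect_identical(nSites(d), 585L)
  expect_identical(nSubsamples(d), 7L)
  expect_identical(sum(rowSums(d@observedMask) == 0), 13L)
  expect_true(all(d@yearIndex[rowSums(d@observedMask) == 0] == 2L))
  ## 2 year-intercepts per submodel, 3 species x 2 submodels
  expect_identical(sum(parameterIndex(sc@graph)$kind == "year"), 12L)
  sim <- simulateDataset(sc)
  expect_true(all(unlist(sim$data@y) <= 7, na.rm = TRUE))
  expect_true(all(is.na(sim$data@y$coyote[196:208, ])))
})
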