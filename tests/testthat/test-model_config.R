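test_that("two-species graph builds the expected parameter index", {
  g <- twoSpeciesGraph()
  expect_s4_class(g, "ModelGraph")
  expect_identical(topologicalOrder(g), c("D", "S"))
  ## dominant state, dominant detection, then subordinate state (intercept,
  ## interaction), then subordinate detection
  expect_identical(parameterIndex(g)$name,
                   c("D_state_int", "D_det_int",
                     "S_state_int", "S_state_gamma0_D", "S_det_int"))
  gm <- buildModelGraph(twoSpeciesConfig(modifier = TRUE))
  expect_identical(parameterIndex(gm)$name,
                   c("D_state_int", "D_det_int", "S_state_int",
                     "S_state_gamma0_D", "S_state_gamma1_D_x_x2",
                     "S_det_int"))
  expect_true("x2" %in% gm@covariateNames)
})

test_that("single species with no edges reduces to a plain Royle-Nichols model", {
  g <- oneSpeciesGraph()
  expect_identical(parameterIndex(g)$name, c("D_state_int", "D_det_int"))
  expect_length(g@species[[1]]@interactions, 0L)
})

test_that("three-species graph orders D, I, S with three interaction parameters", {
  ## declared out of order on purpose
  cfg <- list(species = list(
    list(name = "S", role = "subordinate", state = "occupancy",
         interactions = list(list(source = "I", target = "state"),
                             list(source = "D", target = "state"))),
    list(name = "D", role = "dominant", state = "abundance"),
    list(name = "I", role = "intermediate", state = "abundance",
         interactions = list(list(source = "D", target = "state")))))
  g <- buildModelGraph(cfg)
  expect_identical(topologicalOrder(g), c("D", "I", "S"))
  expect_identical(sum(parameterIndex(g)$kind == "gamma0"), 3L)
})

test_that("cyclic and malformed graphs are configuration errors", {
  cyc <- list(species = list(
    list(name = "D", state = "abundance",
         interactions = list(list(source = "S", target = "state"))),
    list(name = "S", state = "abundance",
         interactions = list(list(source = "D", target = "state")))))
  expect_error(buildModelGraph(cyc), "cycle")
  expect_error(buildModelGraph(list(species = list(
    list(name = "D", state = "abundance",
         interactions = list(list(source = "D", target = "state")))))),
    "self-interaction")
  expect_error(buildModelGraph(list(species = list(
    list(name = "D", state = "abundance",
         interactions = list(list(source = "ghost", target = "state")))))),
    "not a declared species")
  expect_error(buildModelGraph(list(species = list())), "at least one species")
})

test_that("an occupancy-state source requires the occupancy-mediated flag", {
  cfg <- list(species = list(
    list(name = "D", state = "occupancy"),
    list(name = "S", role = "subordinate", state = "occupancy",
         interactions = list(list(source = "D", target = "state")))))
  expect_error(buildModelGraph(cfg), "occupancy-state")
  cfg$occupancy_mediated <- TRUE
  expect_s4_class(buildModelGraph(cfg), "ModelGraph")
})

test_that("parameter index size matches the submodel accounting identity", {
  countFor <- function(g, nYears = 0L) {
    yr <- if (nYears > 1L) nYears - 1L else 0L
    sum(vapply(g@species, function(sp) {
      st <- sum(vapply(sp@interactions, function(e)
        (e@targetSubmodel == "state") * (1L + !is.na(e@modifier)), 0L))
      dt <- sum(vapply(sp@interactions, function(e)
        (e@targetSubmodel == "detection") * (1L + !is.na(e@modifier)), 0L))
      (1L + length(sp@stateFormula) + st + yr) +
        (1L + length(sp@detectionFormula) + dt + yr)
    }, 0L))
  }
  cfgs <- list(
    twoSpeciesConfig(),
    twoSpeciesConfig(modifier = TRUE),
    twoSpeciesConfig(detectionEdge = TRUE),
    list(species = list(
      list(name = "A", state = "abundance",
           state_covariates = list("u", "v"),
           detection_covariates = list("w")),
      list(name = "B", role = "subordinate", state = "abundance",
           interactions = list(list(source = "A", target = "state",
                                    modifier = "u"),
                               list(source = "A", target = "detection")))))
  )
  for (cfg in cfgs) {
    g <- buildModelGraph(cfg)
    expect_identical(nrow(parameterIndex(g)), countFor(g))
    expect_false(anyDuplicated(parameterIndex(g)$name) > 0)
  }
  ## with year intercepts: (nYears - 1) extra per submodel
  cfg <- twoSpeciesConfig(); cfg$year_effects <- TRUE
  design <- studyDesign(9, 2, yearIndex = rep(1:3, each = 3))
  gy <- buildModelGraph(cfg, design)
  expect_identical(nrow(parameterIndex(gy)), countFor(gy, nYears = 3L))
  expect_identical(sum(parameterIndex(gy)$kind == "year"), 2L * 2L * 2L)
})

test_that("a graph rebuilt from its own serialized config is identical", {
  for (g in list(twoSpeciesGraph(), twoSpeciesGraph(modifier = TRUE),
                 asOccupancyMediated(twoSpeciesGraph()))) {
    g2 <- buildModelGraph(graphToConfig(g))
    expect_identical(parameterIndex(g2), parameterIndex(g))
    expect_identical(topologicalOrder(g2), topologicalOrder(g))
    expect_identical(g2@occupancyMediated, g@occupancyMediated)
  }
  ## and through a JSON file on disk
  g <- buildModelGraph(twoSpeciesConfig(modifier = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  writeModelConfig(g, path)
  g3 <- buildModelGraph(readModelConfig(path))
  expect_identical(parameterIndex(g3), parameterIndex(g))
})

test_that("study design invariants are enforced", {
  expect_error(studyDesign(0, 3), "nSites")
  m <- matrix(TRUE, 4, 3); m[2, ] <- FALSE
  expect_error(studyDesign(4, 3, observedMask = m), "no sampled occasion")
  d <- studyDesign(4, 3, observedMask = m, allowEmptySites = TRUE)
  expect_s4_class(d, "StudyDesign")
  expect_error(studyDesign(4, 3, observedMask = matrix(TRUE, 3, 3)),
               "nSites x nOccasions")
  expect_error(interactionTerm("D", target = "both"), "state")
})
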