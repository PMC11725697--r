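## Small builders used across test files. Everything is generated in code;
## no fixture files.

twoSpeciesConfig <- function(modifier = FALSE, detectionEdge = FALSE) {
  int <- list(source = "D",
              target = if (detectionEdge) "detection" else "state")
  if (modifier) int$modifier <- "x2"
  list(species = list(
    list(name = "D", role = "dominant", state = "abundance"),
    list(name = "S", role = "subordinate", state = "occupancy",
         interactions = list(int))))
}

twoSpeciesGraph <- function(...) buildModelGraph(twoSpeciesConfig(...))

## a two-species dataset with explicit counts (K = 1)
tinyData <- function(yD, yS, nOccasions = ncol(yD), mask = NULL,
                     covariates = NULL) {
  I <- nrow(yD)
  design <- studyDesign(I, nOccasions, 1L,
                        observedMask = if (is.null(mask))
                          matrix(TRUE, I, nOccasions) else mask,
                        allowEmptySites = TRUE)
  storage.mode(yD) <- "integer"; storage.mode(yS) <- "integer"
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(I))
  new("DetectionData", y = list(D = yD, S = yS), design = design,
      covariates = covariates, siteIds = as.character(seq_len(I)))
}

## default coefficients for the two-species graph (lambda = 1, r = 0.5,
## psi = 0.5, p = 0.5, gamma0 as given)
tinyCoefs <- function(gamma0 = -1) {
  c(D_state_int = 0, D_det_int = 0, S_state_int = 0,
    S_state_gamma0_D = gamma0, S_det_int = 0)
}

## single abundance species dataset
oneSpeciesData <- function(y, K = 1L, mask = NULL) {
  I <- nrow(y); J <- ncol(y)
  design <- studyDesign(I, J, K,
                        observedMask = if (is.null(mask)) matrix(TRUE, I, J)
                          else mask,
                        allowEmptySites = TRUE)
  storage.mode(y) <- "integer"
  new("DetectionData", y = list(D = y), design = design,
      covariates = data.frame(row.names = seq_len(I)),
      siteIds = as.character(seq_len(I)))
}

oneSpeciesGraph <- function() {
  buildModelGraph(list(species = list(list(name = "D", state = "abundance"))))
}

oneOccupancyGraph <- function() {
  buildModelGraph(list(species = list(list(name = "S", state = "occupancy"))))
}

## short MCMC settings for structural tests (not for inference quality)
shortMcmc <- function(...) {
  mcmcConfig(nIterations = 700, burnIn = 200, thin = 1, ...)
}
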