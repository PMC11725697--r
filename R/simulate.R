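## Generative simulator: draws covariates, latent states in topological order
## and observations from any model graph, plus preset scenario builders for
## the three simulation studies and a case-study-shaped synthetic stand-in.

#' Construct a simulation scenario
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param graph a \linkS4class{ModelGraph}.
#' @param trueValues named numeric covering every parameter in the graph's
#'   index (extra entries are allowed and recorded).
#' @param seed RNG seed for \code{\link{simulateDataset}}.
#' @param covariateSpec covariate generator (currently \code{"std_normal"}).
#' @return a \linkS4class{SimulationScenario}.
#' @export
simulationScenario <- function(design, graph, trueValues, seed = 1L,
                               covariateSpec = "std_normal") {
  new("SimulationScenario", design = design, graph = graph,
      trueValues = trueValues, covariateSpec = covariateSpec,
      seed = as.integer(seed))
}

#' Simulate a dataset from a scenario
#'
#' Draws independent standard-Normal site covariates (empirically
#' standardised to mean 0, sd 1), then species latent states in topological
#' order (\eqn{N \sim Poisson(\lambda_i)} for abundance species, \eqn{z \sim
#' Bernoulli(\psi_i)} for occupancy species, with interaction terms using the
#' realized upstream abundances), then observations: counts over K binomial
#' trials with the Royle-Nichols detection probability for abundance species,
#' Bernoulli detections for occupancy species. Masked cells are NA.
#'
#' @param scenario a \linkS4class{SimulationScenario}.
#' @param seed optional override of the scenario's seed.
#' @return list with \code{data} (a \linkS4class{DetectionData}) and
#'   \code{truth} (true parameter values and the realized latent states).
#' @examples
#' sim <- simulateDataset(presetStudy1(0.5))
#' sim$data
#' @export
simulateDataset <- function(scenario, seed = NULL) {
  design <- scenario@design
  graph <- scenario@graph
  theta <- scenario@trueValues
  set.seed(if (is.null(seed)) scenario@seed else as.integer(seed))

  I <- design@nSites; J <- design@nOccasions; K <- design@nSubsamples
  S <- length(graph@species)
  covs <- as.data.frame(setNames(lapply(graph@covariateNames, function(nm) {
    x <- stats::rnorm(I)
    if (I > 1) as.numeric(scale(x)) else x
  }), graph@covariateNames))
  if (!length(graph@covariateNames))
    covs <- data.frame(row.names = seq_len(I))

  ## placeholder container so design-matrix helpers can be reused
  yEmpty <- lapply(seq_len(S), function(k) matrix(NA_integer_, I, J))
  names(yEmpty) <- speciesNames(graph)
  data <- new("DetectionData", y = yEmpty, design = design,
              covariates = covs, siteIds = as.character(seq_len(I)))

  latentMat <- matrix(0, I, S)
  yList <- list()
  for (k in seq_len(S)) {
    sp <- graph@species[[k]]
    etaS <- .etaVector(graph, data, theta, latentMat, k, "state")
    etaD <- .etaVector(graph, data, theta, latentMat, k, "det")
    if (sp@stateVariable == "abundance") {
      N <- stats::rpois(I, exp(pmin(etaS, 30)))
      latentMat[, k] <- N
      p <- rnDetectionProb(stats::plogis(etaD), N)
      y <- matrix(stats::rbinom(I * J, K, p), I, J)
    } else {
      z <- stats::rbinom(I, 1, stats::plogis(etaS))
      latentMat[, k] <- z
      p <- stats::plogis(etaD) * z
      y <- matrix(stats::rbinom(I * J, 1, p), I, J)
    }
    y[!design@observedMask] <- NA_integer_
    storage.mode(y) <- "integer"
    yList[[sp@name]] <- y
  }
  data@y <- yList
  validObject(data)
  colnames(latentMat) <- speciesNames(graph)
  list(data = data,
       truth = list(values = theta, latent = latentMat))
}

## Poisson pmf over 0..nMax (renormalised tail-truncation for expectations)
.poisGrid <- function(lambda, nMax = 60L) {
  w <- stats::dpois(0:nMax, lambda)
  w / sum(w)
}

## Solve the occupancy intercept b0 so that the scenario-average of
## invlogit(b0 + gamma0*N [+ gamma1*N*x]) over N ~ Poisson(lambda) (and
## x ~ N(0,1) when gamma1 != 0) equals the target mean occupancy.
.solvePsiIntercept <- function(target, gamma0, lambda, gamma1 = 0,
                               nMax = 60L) {
  wN <- .poisGrid(lambda, nMax)
  ns <- 0:nMax
  if (gamma1 == 0) {
    f <- function(b0) sum(wN * stats::plogis(b0 + gamma0 * ns)) - target
  } else {
    xs <- stats::qnorm((seq_len(400) - 0.5) / 400)
    f <- function(b0) {
      m <- outer(ns, xs, function(n, x)
        stats::plogis(b0 + gamma0 * n + gamma1 * n * x))
      sum(wN * rowMeans(m)) - target
    }
  }
  stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
}

## Solve a log-link intercept so the marginal mean abundance equals target,
## given one incoming edge from a Poisson(srcLambda) source: the Poisson
## moment generating function gives E[exp(g0 N)] = exp(srcLambda (e^g0 - 1)).
.solveLambdaIntercept <- function(target, gamma0, srcLambda) {
  log(target) - srcLambda * (exp(gamma0) - 1)
}

.twoSpeciesConfig <- function(varying = FALSE) {
  list(species = list(
    list(name = "D", role = "dominant", state = "abundance"),
    list(name = "S", role = "subordinate", state = "occupancy",
         interactions = list(
           c(list(source = "D", target = "state"),
             if (varying) list(modifier = "x2"))))))
}

#' Preset: occupancy- vs abundance-mediated comparison scenario
#'
#' Two species, constant detection probabilities \eqn{r^D = 0.3},
#' \eqn{p^S = 0.5}, mean subordinate occupancy \eqn{\bar\psi^S = 0.75},
#' constant interaction \eqn{\gamma_0 = -1} (\eqn{\gamma_1 = 0}), I = 600
#' sites, J = 4 occasions, K = 1. The subordinate intercept is solved so the
#' scenario-average occupancy equals the target and is recorded as the truth.
#'
#' @param lambdaD dominant mean abundance; the study considers 0.5, 1 and 2
#'   (other values are allowed with a warning).
#' @param I,J design dimensions (study values by default).
#' @param seed scenario seed.
#' @return a \linkS4class{SimulationScenario}.
#' @export
presetStudy1 <- function(lambdaD, I = 600L, J = 4L, seed = 1L) {
  if (!lambdaD %in% c(0.5, 1, 2))
    warning("lambdaD = ", lambdaD, " extends beyond the studied values 0.5/1/2")
  graph <- buildModelGraph(.twoSpeciesConfig(FALSE))
  design <- studyDesign(I, J, nSubsamples = 1L)
  truths <- c(
    D_state_int = log(lambdaD),
    D_det_int = stats::qlogis(0.3),
    S_state_int = .solvePsiIntercept(0.75, -1, lambdaD),
    S_state_gamma0_D = -1,
    S_state_gamma1_D = 0,  # no modifier in this study; recorded for completeness
    S_det_int = stats::qlogis(0.5))
  simulationScenario(design, graph, truths, seed)
}

#' Preset: two-species sampling-effort scenario
#'
#' Constant detection probabilities \eqn{r^D = 0.5}, \eqn{p^S = 0.5}, mean
#' dominant abundance \eqn{\lambda^D = 1}, mean subordinate occupancy
#' \eqn{\bar\psi^S = 0.5}, \eqn{\gamma_0 = -1}; with \code{varying = TRUE}
#' the interaction is additionally modified by an independent standard-Normal
#' site covariate with \eqn{\gamma_1 = 1}. K = 1.
#'
#' @param I sites (study values 300, 600, 1000).
#' @param J occasions (study values 4, 10).
#' @param varying include the spatially varying interaction term.
#' @param seed scenario seed.
#' @return a \linkS4class{SimulationScenario}.
#' @export
presetStudy2 <- function(I = 300L, J = 4L, varying = FALSE, seed = 1L) {
  if (!I %in% c(300L, 600L, 1000L) || !J %in% c(4L, 10L))
    warning("I = ", I, ", J = ", J,
            " extend beyond the studied designs (I in 300/600/1000, J in 4/10)")
  graph <- buildModelGraph(.twoSpeciesConfig(varying))
  design <- studyDesign(I, J, nSubsamples = 1L)
  truths <- c(
    D_state_int = log(1),
    D_det_int = stats::qlogis(0.5),
    S_state_int = .solvePsiIntercept(0.5, -1, 1, gamma1 = if (varying) 1 else 0),
    S_state_gamma0_D = -1,
    S_det_int = stats::qlogis(0.5))
  if (varying) truths <- c(truths, S_state_gamma1_D_x_x2 = 1)
  simulationScenario(design, graph, truths, seed)
}

#' Preset: three-species scenario with variable detection probabilities
#'
#' Dominant and intermediate species are abundance-state
#' (\eqn{\lambda^D = \lambda^I = 0.5}), the subordinate is occupancy-state
#' (\eqn{\bar\psi^S = 0.5}); constant interactions
#' \eqn{\gamma_0^{D-I} = -1}, \eqn{\gamma_0^{I-S} = -1},
#' \eqn{\gamma_0^{D-S} = +1}; I = 600, J = 4, K = 1; the intermediate
#' detection probability is fixed at \eqn{r^I = 0.5}.
#'
#' @param rD dominant individual detection probability (study range 0.05-0.5).
#' @param pS subordinate detection probability (study range 0.25-0.5).
#' @param seed scenario seed.
#' @return a \linkS4class{SimulationScenario}.
#' @export
presetStudy3 <- function(rD = 0.5, pS = 0.5, seed = 1L) {
  cfg <- list(species = list(
    list(name = "D", role = "dominant", state = "abundance"),
    list(name = "I", role = "intermediate", state = "abundance",
         interactions = list(list(source = "D", target = "state"))),
    list(name = "S", role = "subordinate", state = "occupancy",
         interactions = list(list(source = "I", target = "state"),
                             list(source = "D", target = "state")))))
  graph <- buildModelGraph(cfg)
  design <- studyDesign(600L, 4L, nSubsamples = 1L)

  b0I <- .solveLambdaIntercept(0.5, -1, 0.5)
  ## mean occupancy target over the realized joint distribution of (N_D, N_I)
  wD <- .poisGrid(0.5, 30L)
  f <- function(b0) {
    tot <- 0
    for (nD in 0:30) {
      lamI <- exp(b0I - nD)
      wI <- .poisGrid(lamI, 60L)
      tot <- tot + wD[nD + 1] *
        sum(wI * stats::plogis(b0 + nD - (0:60)))
    }
    tot - 0.5
  }
  b0S <- stats::uniroot(f, c(-25, 25), tol = 1e-10)$root

  truths <- c(
    D_state_int = log(0.5),
    D_det_int = stats::qlogis(rD),
    I_state_int = b0I,
    I_state_gamma0_D = -1,
    I_det_int = stats::qlogis(0.5),
    S_state_int = b0S,
    S_state_gamma0_I = -1,
    S_state_gamma0_D = 1,
    S_det_int = stats::qlogis(pS))
  simulationScenario(design, graph, truths, seed)
}

#' Preset: synthetic case-study-shaped scenario
#'
#' A synthetic stand-in with the shape of the carnivore camera-trap case
#' study: 195 sample units surveyed in each of 3 winters (stacked as 585
#' site-years with year-specific intercepts on every state and detection
#' submodel; 13 site-years masked in year 2), J = 3 weekly occasions whose
#' counts aggregate K = 7 daily subsamples, and three abundance-state species
#' (coyote-, fisher- and marten-like) linked by three constant interaction
#' terms: top predator to both smaller species and intermediate to smallest.
#' All true values are synthetic defaults, not estimates from any dataset.
#'
#' @param seed scenario seed.
#' @param nSitesPerYear sample units per year.
#' @return a \linkS4class{SimulationScenario}.
#' @export
presetCaseStudySynthetic <- function(seed = 1L, nSitesPerYear = 195L) {
  nYears <- 3L
  I <- nSitesPerYear * nYears
  J <- 3L
  yearIndex <- rep(1:nYears, each = nSitesPerYear)
  mask <- matrix(TRUE, I, J)
  masked <- nSitesPerYear + seq_len(13L)  # 13 unsampled site-years in year 2
  mask[masked, ] <- FALSE
  design <- studyDesign(I, J, nSubsamples = 7L, yearIndex = yearIndex,
                        observedMask = mask, allowEmptySites = TRUE)

  cfg <- list(
    species = list(
      list(name = "coyote", role = "dominant", state = "abundance",
           state_covariates = list("forest_edge", "deer")),
      list(name = "fisher", role = "intermediate", state = "abundance",
           state_covariates = list("deciduous", "conifer_mixed", "snow"),
           interactions = list(list(source = "coyote", target = "state"))),
      list(name = "marten", role = "subordinate", state = "abundance",
           state_covariates = list("deciduous", "conifer_mixed", "snow"),
           interactions = list(list(source = "coyote", target = "state"),
                               list(source = "fisher", target = "state")))),
    year_effects = TRUE)
  graph <- buildModelGraph(cfg, design)

  truths <- c(
    coyote_state_int = log(0.6), coyote_state_forest_edge = 0.2,
    coyote_state_deer = 0.2, coyote_state_yr2 = 0.1, coyote_state_yr3 = -0.1,
    coyote_det_int = stats::qlogis(0.12), coyote_det_yr2 = 0.1,
    coyote_det_yr3 = -0.1,
    fisher_state_int = log(0.8), fisher_state_deciduous = 0.25,
    fisher_state_conifer_mixed = 0.35, fisher_state_snow = -0.15,
    fisher_state_yr2 = -0.1, fisher_state_yr3 = 0.1,
    fisher_state_gamma0_coyote = 0.2,
    fisher_det_int = stats::qlogis(0.15), fisher_det_yr2 = 0.1,
    fisher_det_yr3 = 0,
    marten_state_int = log(0.7), marten_state_deciduous = 0.5,
    marten_state_conifer_mixed = 0.5, marten_state_snow = 0.2,
    marten_state_yr2 = 0, marten_state_yr3 = 0.1,
    marten_state_gamma0_coyote = -0.5, marten_state_gamma0_fisher = -0.1,
    marten_det_int = stats::qlogis(0.15), marten_det_yr2 = -0.1,
    marten_det_yr3 = 0.1)
  simulationScenario(design, graph, truths, seed)
}
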