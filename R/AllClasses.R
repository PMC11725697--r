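#' @import methods
NULL

#' Sampling design of a detection/non-detection study
#'
#' Describes the replication structure of an unmarked survey: \code{I} sites
#' visited on up to \code{J} occasions, each occasion consisting of \code{K}
#' subsamples whose detections are summed into a count \code{y} in
#' \code{0..K}. An optional per-site year index supports year-specific
#' intercepts; the observation mask records which site-by-occasion cells were
#' actually sampled.
#'
#' @slot nSites number of sites I.
#' @slot nOccasions number of occasions J.
#' @slot nSubsamples subsamples per occasion K (counts are bounded by K).
#' @slot yearIndex integer vector of length I mapping each site-row to a year
#'   (1-based), or \code{integer(0)} when year effects are not used.
#' @slot observedMask logical I x J matrix, \code{TRUE} where the occasion was
#'   sampled.
#' @export
setClass("StudyDesign",
  representation(
    nSites = "integer",
    nOccasions = "integer",
    nSubsamples = "integer",
    yearIndex = "integer",
    observedMask = "matrix"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@nSites) != 1L || object@nSites < 1L)
    msg <- c(msg, "nSites must be a single integer >= 1")
  if (length(object@nOccasions) != 1L || object@nOccasions < 1L)
    msg <- c(msg, "nOccasions must be a single integer >= 1")
  if (length(object@nSubsamples) != 1L || object@nSubsamples < 1L)
    msg <- c(msg, "nSubsamples must be a single integer >= 1")
  if (!is.logical(object@observedMask))
    msg <- c(msg, "observedMask must be logical")
  if (!all(dim(object@observedMask) == c(object@nSites, object@nOccasions)))
    msg <- c(msg, "observedMask must be an nSites x nOccasions matrix")
  if (length(object@yearIndex) > 0L) {
    if (length(object@yearIndex) != object@nSites)
      msg <- c(msg, "yearIndex must have one entry per site")
    if (any(object@yearIndex < 1L))
      msg <- c(msg, "yearIndex entries must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' A directed abundance-mediated interaction term
#'
#' One edge of the interaction graph: the latent abundance \eqn{N} of
#' \code{source} enters the target species' state or detection linear
#' predictor as \eqn{\gamma_0 N} and, when a modifier covariate \eqn{x} is
#' declared, additionally as \eqn{\gamma_1 N x}.
#'
#' @slot source name of the upstream species.
#' @slot targetSubmodel \code{"state"} or \code{"detection"}.
#' @slot modifier name of the modifying covariate, or \code{NA_character_}.
#' @export
setClass("InteractionTerm",
  representation(
    source = "character",
    targetSubmodel = "character",
    modifier = "character"
  )
)

setValidity("InteractionTerm", function(object) {
  if (!object@targetSubmodel %in% c("state", "detection"))
    return("targetSubmodel must be 'state' or 'detection'")
  TRUE
})

#' One species' submodel within the interaction graph
#'
#' @slot name species identifier.
#' @slot role one of \code{"dominant"}, \code{"intermediate"},
#'   \code{"subordinate"}.
#' @slot stateVariable \code{"abundance"} (Royle-Nichols latent N) or
#'   \code{"occupancy"} (latent binary z).
#' @slot stateFormula covariate names entering the state linear predictor.
#' @slot detectionFormula covariate names entering the detection linear
#'   predictor.
#' @slot interactions list of \linkS4class{InteractionTerm} received by this
#'   species.
#' @export
setClass("SpeciesModel",
  representation(
    name = "character",
    role = "character",
    stateVariable = "character",
    stateFormula = "character",
    detectionFormula = "character",
    interactions = "list"
  )
)

setValidity("SpeciesModel", function(object) {
  msg <- character()
  if (!object@role %in% c("dominant", "intermediate", "subordinate"))
    msg <- c(msg, "role must be dominant, intermediate or subordinate")
  if (!object@stateVariable %in% c("abundance", "occupancy"))
    msg <- c(msg, "stateVariable must be 'abundance' or 'occupancy'")
  if (!all(vapply(object@interactions, inherits, TRUE, "InteractionTerm")))
    msg <- c(msg, "interactions must be InteractionTerm objects")
  if (length(msg)) msg else TRUE
})

#' Validated multispecies model graph
#'
#' The species submodels in topological order of the directed interaction
#' graph, the set of covariate columns the model consumes, and the flat index
#' of all regression and interaction parameters.
#'
#' @slot species list of \linkS4class{SpeciesModel}, topologically ordered so
#'   every interaction source precedes its targets.
#' @slot covariateNames all covariate columns required by any formula or
#'   modifier.
#' @slot parameterIndex data.frame (name, species, submodel, kind, source,
#'   covariate) with one row per parameter; names are unique.
#' @slot occupancyMediated if \code{TRUE}, every upstream contribution is the
#'   indicator \eqn{1\{N > 0\}} instead of \eqn{N} (the occupancy-mediated
#'   comparison variant).
#' @slot yearEffects whether year-specific intercepts are included in every
#'   state and detection submodel (dummy coding, first year as reference).
#' @slot nYears number of year levels (0 when yearEffects is off).
#' @export
setClass("ModelGraph",
  representation(
    species = "list",
    covariateNames = "character",
    parameterIndex = "data.frame",
    occupancyMediated = "logical",
    yearEffects = "logical",
    nYears = "integer"
  )
)

setValidity("ModelGraph", function(object) {
  msg <- character()
  if (!all(vapply(object@species, inherits, TRUE, "SpeciesModel")))
    msg <- c(msg, "species must be SpeciesModel objects")
  if (anyDuplicated(object@parameterIndex$name))
    msg <- c(msg, "parameterIndex has duplicate parameter names")
  nm <- vapply(object@species, function(s) s@name, "")
  if (anyDuplicated(nm))
    msg <- c(msg, "duplicate species names")
  ## every edge source must precede its target in the stored order
  for (k in seq_along(object@species)) {
    for (e in object@species[[k]]@interactions) {
      src <- match(e@source, nm)
      if (is.na(src)) msg <- c(msg, paste0("unknown source species ", e@source))
      else if (src >= k)
        msg <- c(msg, paste0("species ", nm[k], " precedes its source ", e@source))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Detection/non-detection data for a multispecies study
#'
#' Per-species count matrices \code{y[i, j]} in \code{0..K} (for
#' abundance-state species) or \code{{0, 1}} (for occupancy-state species),
#' stored with \code{NA} in masked cells, together with the design and the
#' site covariate table shared by all species.
#'
#' @slot y named list of integer I x J matrices, one per species; masked
#'   cells are \code{NA}, never 0.
#' @slot design the \linkS4class{StudyDesign}.
#' @slot covariates data.frame with one row per site.
#' @slot siteIds stable site identifiers.
#' @export
setClass("DetectionData",
  representation(
    y = "list",
    design = "StudyDesign",
    covariates = "data.frame",
    siteIds = "character"
  )
)

setValidity("DetectionData", function(object) {
  msg <- character()
  d <- object@design
  K <- d@nSubsamples
  for (nm in names(object@y)) {
    m <- object@y[[nm]]
    if (!all(dim(m) == c(d@nSites, d@nOccasions))) {
      msg <- c(msg, paste0("y[[", nm, "]] has wrong dimensions"))
      next
    }
    bad <- !is.na(m) & (m < 0L | m > K)
    if (any(bad))
      msg <- c(msg, paste0("y[[", nm, "]] has counts outside 0..K"))
    if (any(!is.na(m) & !d@observedMask))
      msg <- c(msg, paste0("y[[", nm, "]] has values in masked cells"))
  }
  if (nrow(object@covariates) > 0L && nrow(object@covariates) != d@nSites)
    msg <- c(msg, "covariates must have one row per site")
  if (length(object@siteIds) != d@nSites)
    msg <- c(msg, "siteIds must have one entry per site")
  if (length(msg)) msg else TRUE
})

#' A fully specified generative scenario
#'
#' Everything needed to simulate datasets from the model: the design, the
#' interaction graph, a true value for every parameter in the graph's index,
#' and the covariate generator.
#'
#' @slot design a \linkS4class{StudyDesign}.
#' @slot graph a \linkS4class{ModelGraph}.
#' @slot trueValues named numeric vector covering graph parameterIndex.
#' @slot covariateSpec covariate generator; currently \code{"std_normal"}
#'   (independent standard-Normal site covariates, empirically standardised).
#' @slot seed base RNG seed.
#' @export
setClass("SimulationScenario",
  representation(
    design = "StudyDesign",
    graph = "ModelGraph",
    trueValues = "numeric",
    covariateSpec = "character",
    seed = "integer"
  )
)

setValidity("SimulationScenario", function(object) {
  need <- object@graph@parameterIndex$name
  miss <- setdiff(need, names(object@trueValues))
  if (length(miss))
    return(paste0("missing true values for: ", paste(miss, collapse = ", ")))
  TRUE
})

#' Posterior sample with summaries and diagnostics
#'
#' @slot draws list with one (retained draws x parameters) matrix per chain.
#' @slot parameters parameter names (columns of each draws matrix).
#' @slot summaries data.frame: parameter, mode, mean, sd, lo95, hi95, rhat,
#'   rhatUpper, ess.
#' @slot rhat data.frame: parameter, point, upper (NA with a single chain).
#' @slot converged \code{TRUE} iff every parameter's R-hat upper CI < 1.1
#'   (NA with a single chain).
#' @slot ppc named numeric of per-species Bayesian p-values (empty until
#'   \code{\link{ppcPearson}} is run).
#' @slot latent list of saved latent-state draws per chain (possibly empty).
#' @slot mcmc list echoing the MCMC configuration and seeds used.
#' @slot graph the fitted \linkS4class{ModelGraph}.
#' @export
setClass("PosteriorResult",
  representation(
    draws = "list",
    parameters = "character",
    summaries = "data.frame",
    rhat = "data.frame",
    converged = "logical",
    ppc = "numeric",
    latent = "list",
    mcmc = "list",
    graph = "ModelGraph"
  )
)
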