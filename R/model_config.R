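## Model declaration: species roles, directed interaction graph, covariate
## structure, and the flat parameter index consumed by the sampler.

#' Construct a study design
#'
#' @param nSites number of sites I (site-rows; a site surveyed in several
#'   years contributes one row per year).
#' @param nOccasions number of occasions J.
#' @param nSubsamples subsamples per occasion K; counts y are bounded by K.
#' @param yearIndex optional integer vector (length I) of 1-based year levels.
#' @param observedMask optional logical I x J matrix; defaults to all TRUE.
#' @param allowEmptySites permit site-rows whose mask is all FALSE (used for
#'   designs carrying unsampled site-years); by default such rows are
#'   rejected as a data error.
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' studyDesign(10, 4)
#' @export
studyDesign <- function(nSites, nOccasions, nSubsamples = 1L,
                        yearIndex = integer(0), observedMask = NULL,
                        allowEmptySites = FALSE) {
  nSites <- as.integer(nSites); nOccasions <- as.integer(nOccasions)
  if (is.null(observedMask))
    observedMask <- matrix(TRUE, nSites, nOccasions)
  d <- new("StudyDesign", nSites = nSites, nOccasions = nOccasions,
           nSubsamples = as.integer(nSubsamples),
           yearIndex = as.integer(yearIndex), observedMask = observedMask)
  if (!allowEmptySites && any(rowSums(observedMask) == 0L))
    stop("design has site(s) with no sampled occasion; ",
         "drop them or pass allowEmptySites = TRUE")
  d
}

#' Construct an interaction term
#'
#' @param source name of the upstream species whose latent abundance enters
#'   the target's linear predictor.
#' @param target \code{"state"} or \code{"detection"}.
#' @param modifier optional covariate name x; when present the edge
#'   contributes \eqn{\gamma_0 N + \gamma_1 N x}, otherwise \eqn{\gamma_0 N}.
#' @return an \linkS4class{InteractionTerm}.
#' @export
interactionTerm <- function(source, target = "state", modifier = NA_character_) {
  new("InteractionTerm", source = source, targetSubmodel = target,
      modifier = as.character(modifier))
}

#' Construct one species submodel
#'
#' @param name species identifier.
#' @param role a priori role: \code{"dominant"}, \code{"intermediate"} or
#'   \code{"subordinate"}.
#' @param state \code{"abundance"} or \code{"occupancy"}.
#' @param stateCovariates covariate names for the state linear predictor.
#' @param detectionCovariates covariate names for the detection predictor.
#' @param interactions list of \code{\link{interactionTerm}} received by this
#'   species.
#' @return a \linkS4class{SpeciesModel}.
#' @export
speciesModel <- function(name, role = "dominant", state = "abundance",
                         stateCovariates = character(0),
                         detectionCovariates = character(0),
                         interactions = list()) {
  new("SpeciesModel", name = name, role = role, stateVariable = state,
      stateFormula = as.character(stateCovariates),
      detectionFormula = as.character(detectionCovariates),
      interactions = interactions)
}

.roleRank <- c(dominant = 1L, intermediate = 2L, subordinate = 3L)

## Kahn topological sort with deterministic tie-break: role rank, then
## declaration order. Cycles raise a configuration error.
.topoSort <- function(splist) {
  nm <- vapply(splist, function(s) s@name, "")
  n <- length(splist)
  indeg <- integer(n)
  adj <- vector("list", n)  # adj[[src]] = targets
  for (k in seq_len(n)) {
    for (e in splist[[k]]@interactions) {
      src <- match(e@source, nm)
      if (is.na(src))
        stop("configuration error: interaction source '", e@source,
             "' is not a declared species")
      if (src == k)
        stop("configuration error: self-interaction on species '", nm[k], "'")
      adj[[src]] <- c(adj[[src]], k)
      indeg[k] <- indeg[k] + 1L
    }
  }
  rank <- .roleRank[vapply(splist, function(s) s@role, "")]
  ord <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    pick <- avail[order(rank[avail], avail)][1L]
    ord <- c(ord, pick)
    for (t in adj[[pick]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) avail <- c(avail, t)
    }
    avail <- setdiff(avail, pick)
  }
  if (length(ord) != n)
    stop("configuration error: interaction graph contains a cycle")
  ord
}

.gammaBaseName <- function(target, submodel, source)
  paste0(target, "_", submodel, "_gamma0_", source)

## Build the flat parameter index for one ordered species list.
.buildParameterIndex <- function(splist, nYears) {
  rows <- list()
  add <- function(name, species, submodel, kind, source = NA_character_,
                  covariate = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, species = species, submodel = submodel, kind = kind,
      source = source, covariate = covariate, stringsAsFactors = FALSE)
  }
  yrTags <- if (nYears > 1L) paste0("yr", 2:nYears) else character(0)
  for (sp in splist) {
    for (sub in c("state", "det")) {
      covs <- if (sub == "state") sp@stateFormula else sp@detectionFormula
      add(paste0(sp@name, "_", sub, "_int"), sp@name, sub, "intercept")
      for (cv in covs)
        add(paste0(sp@name, "_", sub, "_", cv), sp@name, sub, "covariate",
            covariate = cv)
      for (yt in yrTags)
        add(paste0(sp@name, "_", sub, "_", yt), sp@name, sub, "year")
      tgt <- if (sub == "state") "state" else "detection"
      for (e in sp@interactions) {
        if (e@targetSubmodel != tgt) next
        add(.gammaBaseName(sp@name, sub, e@source), sp@name, sub, "gamma0",
            source = e@source)
        if (!is.na(e@modifier))
          add(paste0(sp@name, "_", sub, "_gamma1_", e@source, "_x_", e@modifier),
              sp@name, sub, "gamma1", source = e@source, covariate = e@modifier)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build and validate a multispecies model graph
#'
#' Accepts either a configuration list (see Details) or a path to a JSON
#' configuration file, resolves the topological order of the directed
#' interaction graph, and assembles the flat parameter index.
#'
#' @details The configuration is a list with elements:
#' \describe{
#'   \item{species}{list of species entries: \code{name}, \code{role},
#'     \code{state} ("abundance"/"occupancy"), \code{state_covariates},
#'     \code{detection_covariates}, and \code{interactions}, each interaction
#'     having \code{source}, \code{target} ("state"/"detection") and optional
#'     \code{modifier}.}
#'   \item{occupancy_mediated}{logical; fit the comparison variant in which
#'     upstream abundance enters as the indicator \eqn{1\{N>0\}}.}
#'   \item{year_effects}{logical; add year-specific intercepts (dummy coded,
#'     first year reference) to every state and detection submodel. Requires
#'     \code{design} (or \code{n_years}) to know the number of levels.}
#' }
#' Optional \code{mcmc} and \code{priors} entries are not consumed here; they
#' are read by \code{\link{fitModel}} wrappers via \code{\link{readModelConfig}}.
#'
#' A species whose state variable is occupancy cannot be the source of an
#' interaction (interactions are mediated by abundance) unless the
#' occupancy-mediated comparison variant is flagged.
#'
#' @param config list or path to a JSON file.
#' @param design optional \linkS4class{StudyDesign} supplying the year index
#'   when \code{year_effects} is on.
#' @return a \linkS4class{ModelGraph}.
#' @examples
#' cfg <- list(species = list(
#'   list(name = "D", role = "dominant", state = "abundance"),
#'   list(name = "S", role = "subordinate", state = "occupancy",
#'        interactions = list(list(source = "D", target = "state")))))
#' g <- buildModelGraph(cfg)
#' topologicalOrder(g)
#' @export
buildModelGraph <- function(config, design = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- readModelConfig(config)
  if (is.null(config$species) || length(config$species) < 1L)
    stop("configuration error: at least one species must be declared")
  splist <- lapply(config$species, function(s) {
    ints <- lapply(s$interactions, function(e)
      interactionTerm(e$source,
                      if (is.null(e$target)) "state" else e$target,
                      if (is.null(e$modifier)) NA_character_ else e$modifier))
    speciesModel(
      name = s$name,
      role = if (is.null(s$role)) "dominant" else s$role,
      state = if (is.null(s$state)) "abundance" else s$state,
      stateCovariates = unlist(s$state_covariates) %||% character(0),
      detectionCovariates = unlist(s$detection_covariates) %||% character(0),
      interactions = ints)
  })
  occMed <- isTRUE(config$occupancy_mediated)
  yearEff <- isTRUE(config$year_effects)

  ord <- .topoSort(splist)
  splist <- splist[ord]
  nm <- vapply(splist, function(s) s@name, "")

  ## abundance mediation requires abundance-state sources unless the
  ## comparison variant is explicitly flagged
  stv <- vapply(splist, function(s) s@stateVariable, "")
  for (sp in splist) for (e in sp@interactions) {
    if (stv[match(e@source, nm)] == "occupancy" && !occMed)
      stop("configuration error: occupancy-state species '", e@source,
           "' cannot source an interaction unless occupancy_mediated is set")
  }

  nYears <- 0L
  if (yearEff) {
    if (!is.null(design) && length(design@yearIndex))
      nYears <- max(design@yearIndex)
    else if (!is.null(config$n_years))
      nYears <- as.integer(config$n_years)
    else
      stop("configuration error: year_effects requires a design with a ",
           "yearIndex (or config$n_years)")
    if (nYears < 2L)
      stop("configuration error: year_effects needs at least 2 year levels")
  }

  covNames <- unique(unlist(lapply(splist, function(s) c(
    s@stateFormula, s@detectionFormula,
    vapply(s@interactions, function(e) e@modifier, "")))))
  covNames <- covNames[!is.na(covNames)]

  pidx <- .buildParameterIndex(splist, nYears)
  new("ModelGraph", species = splist, covariateNames = covNames,
      parameterIndex = pidx, occupancyMediated = occMed,
      yearEffects = yearEff, nYears = nYears)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Switch a graph to the occupancy-mediated comparison variant
#'
#' Returns the same graph with every upstream contribution replaced by the
#' indicator \eqn{1\{N > 0\}}; parameters, order and index are unchanged.
#'
#' @param graph a \linkS4class{ModelGraph}.
#' @param value set (default) or unset the variant flag.
#' @export
asOccupancyMediated <- function(graph, value = TRUE) {
  graph@occupancyMediated <- isTRUE(value)
  graph
}

#' Read / write a model configuration JSON file
#'
#' @param path file path.
#' @return \code{readModelConfig}: the configuration list (species, flags and
#'   any \code{mcmc} / \code{priors} entries).
#' @export
readModelConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' @rdname readModelConfig
#' @param config a configuration list or a \linkS4class{ModelGraph}.
#' @export
writeModelConfig <- function(config, path) {
  if (is(config, "ModelGraph")) config <- graphToConfig(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Serialize a model graph back to its configuration list
#'
#' \code{buildModelGraph(graphToConfig(g))} reproduces \code{g} (round-trip
#' identity).
#'
#' @param graph a \linkS4class{ModelGraph}.
#' @export
graphToConfig <- function(graph) {
  species <- lapply(graph@species, function(s) list(
    name = s@name, role = s@role, state = s@stateVariable,
    state_covariates = as.list(s@stateFormula),
    detection_covariates = as.list(s@detectionFormula),
    interactions = lapply(s@interactions, function(e) {
      out <- list(source = e@source, target = e@targetSubmodel)
      if (!is.na(e@modifier)) out$modifier <- e@modifier
      out
    })))
  out <- list(species = species,
              occupancy_mediated = graph@occupancyMediated,
              year_effects = graph@yearEffects)
  if (graph@yearEffects) out$n_years <- graph@nYears
  out
}

## ---- accessors & show ------------------------------------------------------

#' @rdname StudyDesign-class
#' @export
setMethod("nSites", "StudyDesign", function(object) object@nSites)
#' @rdname StudyDesign-class
#' @export
setMethod("nOccasions", "StudyDesign", function(object) object@nOccasions)
#' @rdname StudyDesign-class
#' @export
setMethod("nSubsamples", "StudyDesign", function(object) object@nSubsamples)
#' @rdname StudyDesign-class
#' @export
setMethod("nSites", "DetectionData", function(object) object@design@nSites)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ModelGraph",
          function(object) vapply(object@species, function(s) s@name, ""))
#' @rdname speciesNames
#' @export
setMethod("speciesNames", "DetectionData", function(object) names(object@y))

#' @rdname parameterIndex
#' @export
setMethod("parameterIndex", "ModelGraph", function(object) object@parameterIndex)
#' @rdname parameterIndex
#' @export
setMethod("parameterIndex", "SimulationScenario",
          function(object) object@graph@parameterIndex)

#' @rdname topologicalOrder
#' @export
setMethod("topologicalOrder", "ModelGraph",
          function(object) speciesNames(object))

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nSites, "sites x", object@nOccasions,
      "occasions, K =", object@nSubsamples, "\n")
  if (length(object@yearIndex))
    cat("  years:", max(object@yearIndex), "levels\n")
  nm <- sum(!object@observedMask)
  if (nm) cat("  masked cells:", nm, "\n")
})

setMethod("show", "ModelGraph", function(object) {
  cat("ModelGraph with", length(object@species), "species",
      if (object@occupancyMediated) "(occupancy-mediated variant)" else "", "\n")
  for (sp in object@species) {
    cat("  ", sp@name, " [", sp@role, ", ", sp@stateVariable, "]", sep = "")
    for (e in sp@interactions)
      cat("  <- ", e@source, " (", e@targetSubmodel,
          if (!is.na(e@modifier)) paste0(", x ", e@modifier), ")", sep = "")
    cat("\n")
  }
  cat("  parameters:", nrow(object@parameterIndex), "\n")
})

setMethod("show", "DetectionData", function(object) {
  d <- object@design
  cat("DetectionData:", length(object@y), "species,",
      d@nSites, "sites x", d@nOccasions, "occasions, K =", d@nSubsamples, "\n")
  for (nm in names(object@y)) {
    m <- object@y[[nm]]
    cat("  ", nm, ": naive detection rate ",
        sprintf("%.3f", mean(m > 0, na.rm = TRUE)), "\n", sep = "")
  }
})

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario (seed ", object@seed, ")\n", sep = "")
  show(object@design)
  show(object@graph)
})
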