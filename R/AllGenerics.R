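#' @rdname StudyDesign-class
#' @param object a package object.
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname StudyDesign-class
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))

#' @rdname StudyDesign-class
#' @export
setGeneric("nSubsamples", function(object) standardGeneric("nSubsamples"))

#' Species names of a model graph or dataset
#' @param object a \linkS4class{ModelGraph} or \linkS4class{DetectionData}.
#' @return character vector of species names.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' Flat parameter index of a model graph
#'
#' One row per parameter (regression coefficients, year intercepts and
#' interaction coefficients), in the stable order used by the sampler.
#'
#' @param object a \linkS4class{ModelGraph} (or an object carrying one).
#' @return data.frame with columns name, species, submodel, kind, source,
#'   covariate.
#' @export
setGeneric("parameterIndex", function(object) standardGeneric("parameterIndex"))

#' Topological order of the species in an interaction graph
#'
#' @param object a \linkS4class{ModelGraph}.
#' @return character vector of species names; every interaction source
#'   precedes its targets.
#' @export
setGeneric("topologicalOrder", function(object) standardGeneric("topologicalOrder"))

#' Posterior draws
#' @param object a \linkS4class{PosteriorResult}.
#' @param combine if \code{TRUE}, rbind all chains into one matrix.
#' @return list of per-chain draw matrices, or a single matrix.
#' @export
setGeneric("draws", function(object, combine = FALSE) standardGeneric("draws"))

#' Posterior summary table
#' @param object a \linkS4class{PosteriorResult}.
#' @return data.frame: parameter, mode, mean, sd, lo95, hi95, rhat,
#'   rhatUpper, ess.
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))

#' Convergence flag
#'
#' \code{TRUE} iff the Gelman-Rubin upper confidence limit is below 1.1 for
#' every parameter; \code{NA} when only one chain was run.
#'
#' @param object a \linkS4class{PosteriorResult}.
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
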