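## Batch simulate-fit-evaluate harness: relative/absolute bias, coverage,
## Type S/M error classification, convergence filtering.

#' Relative bias of a point estimate
#'
#' \eqn{RB = (\hat\theta - \theta) / \theta}, defined for nonzero truths.
#'
#' @param estimate point estimate(s).
#' @param truth true value (nonzero).
#' @export
relativeBias <- function(estimate, truth) {
  if (any(truth == 0))
    stop("relative bias is undefined for a true value of 0; use absoluteBias()")
  (estimate - truth) / truth
}

#' Absolute bias of a point estimate
#'
#' \eqn{AB = \hat\theta - \theta}; the reported bias measure for parameters
#' whose true value is zero.
#'
#' @inheritParams relativeBias
#' @export
absoluteBias <- function(estimate, truth) estimate - truth

#' Coverage of credible intervals
#'
#' Fraction of intervals containing the truth; an endpoint exactly at the
#' truth counts as covered.
#'
#' @param cris two-column matrix (lo, hi) or list of length-2 vectors.
#' @param truth true value.
#' @export
coverage <- function(cris, truth) {
  if (is.list(cris)) cris <- do.call(rbind, cris)
  if (!nrow(cris)) stop("at least one interval is required")
  mean(cris[, 1] <= truth & truth <= cris[, 2])
}

#' Classify estimation error as unbiased, Type M or Type S
#'
#' Type S (sign): the estimated direction opposes the truth. Otherwise Type M
#' (magnitude) when the mean relative bias exceeds the threshold in absolute
#' value; otherwise unbiased.
#'
#' @param meanRb mean relative bias across replicate fits.
#' @param truthSign sign of the true value (+1/-1).
#' @param estimateSign sign of the (mean) estimate.
#' @param threshold unbiasedness threshold on |mean RB| (default 0.05).
#' @return one of \code{"type_S"}, \code{"type_M"}, \code{"unbiased"}.
#' @export
classifyError <- function(meanRb, truthSign, estimateSign, threshold = 0.05) {
  if (sign(estimateSign) != sign(truthSign)) return("type_S")
  if (is.na(meanRb) || abs(meanRb) > threshold) return("type_M")
  "unbiased"
}

#' Run a simulation study
#'
#' For each replicate k, simulates a dataset from the scenario with seed
#' \code{baseSeed + k} and fits the requested model variant(s): the
#' correctly specified abundance-mediated model, and/or the
#' occupancy-mediated comparison variant in which upstream abundance enters
#' as the indicator \eqn{1\{N>0\}}. Fits whose Gelman-Rubin upper CI reaches
#' 1.1 for any parameter are excluded from the metrics (but counted in
#' \code{nTotal}); point estimates are posterior modes (means are also
#' recorded for sensitivity).
#'
#' @param scenarioBuilder function(seed) returning a
#'   \linkS4class{SimulationScenario} (e.g. a wrapped preset), or a single
#'   scenario to be re-seeded per replicate.
#' @param nReps number of replicate datasets (>= 2).
#' @param variants subset of \code{c("abundance", "occupancy")}.
#' @param mcmc an \code{\link{mcmcConfig}}; each replicate offsets the seed
#'   deterministically.
#' @param baseSeed base seed for dataset simulation.
#' @param verbose print one line per replicate.
#' @return list with \code{results} (tidy per-rep, per-parameter data.frame)
#'   and \code{summary} (per-variant, per-parameter evaluation metrics:
#'   truth, meanRb, meanAbsRb, mcSeRb, meanAb, coverage, typeSRate,
#'   classification, nConverged, nTotal).
#' @export
runStudy <- function(scenarioBuilder, nReps, variants = "abundance",
                     mcmc = mcmcConfig(), baseSeed = 1L, verbose = FALSE) {
  stopifnot(nReps >= 2)
  variants <- match.arg(variants, c("abundance", "occupancy"),
                        several.ok = TRUE)
  builder <- if (is.function(scenarioBuilder)) scenarioBuilder
             else function(seed) {
               sc <- scenarioBuilder; sc@seed <- as.integer(seed); sc
             }
  rows <- list()
  for (k in seq_len(nReps)) {
    scenario <- builder(baseSeed + k)
    sim <- simulateDataset(scenario)
    for (v in variants) {
      graph <- if (v == "occupancy") asOccupancyMediated(scenario@graph)
               else scenario@graph
      mc <- mcmc
      mc$seed <- as.integer(mcmc$seed + 1000L * k)
      fit <- tryCatch(
        suppressWarnings(fitModel(graph, sim$data, mc)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        if (verbose) message("rep ", k, " [", v, "] failed: ",
                             conditionMessage(fit))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, rep = k, parameter = scenario@graph@parameterIndex$name,
          mode = NA_real_, mean = NA_real_, lo95 = NA_real_, hi95 = NA_real_,
          converged = FALSE, failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      s <- posteriorSummary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, rep = k, parameter = s$parameter,
        mode = s$mode, mean = s$mean, lo95 = s$lo95, hi95 = s$hi95,
        converged = isTRUE(isConverged(fit)), failed = FALSE,
        stringsAsFactors = FALSE)
      if (verbose)
        message("rep ", k, " [", v, "] converged: ", isConverged(fit))
    }
  }
  results <- do.call(rbind, rows)
  truths <- builder(baseSeed + 1L)@trueValues
  list(results = results,
       summary = summarizeStudy(results, truths),
       truths = truths)
}

#' Summarize study results into evaluation metrics
#'
#' Metrics are computed over converged fits only; failed or non-converged
#' replicates remain in \code{nTotal}.
#'
#' @param results the per-rep results data.frame from \code{\link{runStudy}}.
#' @param truths named numeric of true parameter values.
#' @param threshold unbiasedness threshold for the error classification.
#' @return per-variant, per-parameter data.frame of evaluation metrics.
#' @export
summarizeStudy <- function(results, truths, threshold = 0.05) {
  out <- list()
  for (v in unique(results$variant)) {
    for (p in unique(results$parameter)) {
      if (!p %in% names(truths)) next
      truth <- truths[[p]]
      sub <- results[results$variant == v & results$parameter == p, ]
      conv <- sub[sub$converged %in% TRUE, ]
      n <- nrow(conv)
      if (truth != 0 && n > 0) {
        rb <- relativeBias(conv$mode, truth)
        meanRb <- mean(rb); meanAbsRb <- mean(abs(rb))
        mcSe <- if (n > 1) stats::sd(rb) / sqrt(n) else NA_real_
        meanAb <- mean(absoluteBias(conv$mode, truth))
        cls <- classifyError(meanRb, sign(truth), sign(mean(conv$mode)),
                             threshold)
        tsr <- mean(sign(conv$mode) != sign(truth))
      } else if (n > 0) {
        ab <- absoluteBias(conv$mode, truth)
        meanRb <- NA_real_; meanAbsRb <- NA_real_
        meanAb <- mean(ab)
        mcSe <- if (n > 1) stats::sd(ab) / sqrt(n) else NA_real_
        cls <- if (abs(meanAb) <= threshold) "unbiased" else "type_M"
        tsr <- NA_real_
      } else {
        meanRb <- meanAbsRb <- meanAb <- mcSe <- tsr <- NA_real_
        cls <- NA_character_
      }
      cov <- if (n > 0) coverage(as.matrix(conv[, c("lo95", "hi95")]), truth)
             else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        variant = v, parameter = p, truth = truth,
        meanRb = meanRb, meanAbsRb = meanAbsRb, mcSeRb = mcSe,
        meanAb = meanAb, coverage = cov, typeSRate = tsr,
        classification = cls, nConverged = n, nTotal = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
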