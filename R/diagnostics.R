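## Convergence diagnostics, posterior summaries, posterior predictive checks.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF with its 97.5\% upper confidence limit
#' (Brooks-Gelman correction), computed by \code{coda::gelman.diag}.
#' Convergence is declared in this package when every parameter's upper limit
#' is below 1.1.
#'
#' @param chains either a list of per-chain draw matrices (same named
#'   columns), or a list of per-chain numeric vectors for a single parameter.
#' @return list with numeric vectors \code{point} and \code{upper} (one entry
#'   per parameter; \code{NA} when fewer than two chains are supplied).
#' @examples
#' set.seed(1)
#' gelmanRubin(list(rnorm(500), rnorm(500)))          # ~1
#' gelmanRubin(list(rnorm(500), rnorm(500, 5)))$point # >> 1.1
#' @export
gelmanRubin <- function(chains) {
  if (!is.list(chains)) stop("chains must be a list (one element per chain)")
  vec <- !is.matrix(chains[[1]])
  if (vec) chains <- lapply(chains, function(x) matrix(x, ncol = 1))
  P <- ncol(chains[[1]])
  if (length(chains) < 2L)
    return(list(point = rep(NA_real_, P), upper = rep(NA_real_, P)))
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  gd <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf
  point <- gd[, 1]; upper <- gd[, 2]
  ## a parameter with (numerically) zero between+within variance is stable
  pooled <- apply(do.call(rbind, chains), 2, stats::sd)
  fix <- !is.finite(point) & pooled < 1e-12
  point[fix] <- 1; upper[fix] <- 1
  list(point = unname(point), upper = unname(upper))
}

#' Effective sample size of retained draws
#'
#' @param chains list of per-chain draw matrices or vectors.
#' @return numeric vector, one entry per parameter.
#' @export
effectiveSizeDraws <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  if (!is.matrix(chains[[1]]))
    chains <- lapply(chains, function(x) matrix(x, ncol = 1))
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  unname(coda::effectiveSize(ml))
}

#' Histogram posterior mode
#'
#' Midpoint of the highest-count bin of a fixed 512-bin histogram spanning
#' the range of the draws (deterministic and reproducible, unlike kernel
#' density maximisers).
#'
#' @param x numeric vector of posterior draws.
#' @return the mode estimate.
#' @export
posteriorMode <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 513L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  k <- which.max(tabulate(bin, nbins = 512L))
  (br[k] + br[k + 1]) / 2
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at (1 - level)/2 and 1 - (1 - level)/2.
#'
#' @param x numeric vector of posterior draws.
#' @param level interval mass (default 0.95).
#' @return numeric length-2 vector (lo, hi).
#' @export
equalTailedCri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), names = FALSE))
}

## site-level linear predictor vector for one species/submodel at one theta
## and one latent configuration (I x S matrix)
.etaVector <- function(graph, data, theta, latentMat, speciesIdx, sub) {
  sp <- graph@species[[speciesIdx]]
  X <- .designMatrix(sp, sub, data, graph)
  pidx <- graph@parameterIndex
  sel <- pidx$species == sp@name & pidx$submodel == sub &
    pidx$kind %in% c("intercept", "covariate", "year")
  eta <- as.numeric(X %*% theta[pidx$name[sel]])
  tgt <- if (sub == "state") "state" else "detection"
  spn <- speciesNames(graph)
  for (e in sp@interactions) {
    if (e@targetSubmodel != tgt) next
    v <- latentMat[, match(e@source, spn)]
    f <- if (graph@occupancyMediated) as.numeric(v > 0) else v
    eta <- eta + theta[[.gammaBaseName(sp@name, sub, e@source)]] * f
    if (!is.na(e@modifier))
      eta <- eta + theta[[paste0(sp@name, "_", sub, "_gamma1_", e@source,
                                 "_x_", e@modifier)]] *
        f * data@covariates[[e@modifier]]
  }
  eta
}

#' Posterior predictive check with a Pearson chi-square discrepancy
#'
#' For each retained posterior draw (with its saved latent states), computes
#' \eqn{T(y, \theta) = \sum_{ij} (y_{ij} - E[y_{ij}])^2 / (Var[y_{ij}] + 0.5)}
#' over unmasked cells, with expectation and variance from the binomial or
#' Bernoulli observation model conditional on the drawn latent states;
#' simulates a replicate dataset from the same observation model; and reports
#' the Bayesian p-value \eqn{P(T(y_{rep}) \ge T(y))}. The +0.5 variance floor
#' stabilises cells with near-zero predicted variance.
#'
#' @param fit a \linkS4class{PosteriorResult} from
#'   \code{fitModel(..., saveLatent = TRUE)}.
#' @param data the fitted \linkS4class{DetectionData}.
#' @param species species name to check.
#' @param nRep number of posterior draws to use (default: up to 500).
#' @return the Bayesian p-value.
#' @export
ppcPearson <- function(fit, data, species, nRep = NULL) {
  if (!length(fit@latent))
    stop("fit must be run with saveLatent = TRUE for posterior predictive checks")
  graph <- fit@graph
  spIdx <- match(species, speciesNames(graph))
  if (is.na(spIdx)) stop("unknown species ", species)
  sp <- graph@species[[spIdx]]
  I <- data@design@nSites
  S <- length(graph@species)
  K <- data@design@nSubsamples
  y <- data@y[[species]]
  use <- !is.na(y) & data@design@observedMask

  allDraws <- do.call(rbind, fit@draws)
  allLat <- do.call(rbind, fit@latent)
  nTot <- nrow(allDraws)
  if (is.null(nRep)) nRep <- min(500L, nTot)
  pick <- if (nRep >= nTot) seq_len(nTot)
          else round(seq(1, nTot, length.out = nRep))

  exceed <- 0L
  for (d in pick) {
    theta <- allDraws[d, ]
    latentMat <- matrix(allLat[d, ], I, S)
    etaD <- .etaVector(graph, data, theta, latentMat, spIdx, "det")
    if (sp@stateVariable == "abundance") {
      N <- latentMat[, spIdx]
      p <- rnDetectionProb(stats::plogis(etaD), N)
      E <- K * p; V <- K * p * (1 - p)
      yr <- matrix(stats::rbinom(I * ncol(y), K, rep(p, ncol(y))), I)
    } else {
      z <- latentMat[, spIdx]
      pz <- stats::plogis(etaD) * z
      E <- pz; V <- pz * (1 - pz)
      yr <- matrix(stats::rbinom(I * ncol(y), 1, rep(pz, ncol(y))), I)
    }
    Em <- matrix(E, I, ncol(y)); Vm <- matrix(V, I, ncol(y))
    tObs <- sum(((y[use] - Em[use])^2) / (Vm[use] + 0.5))
    tRep <- sum(((yr[use] - Em[use])^2) / (Vm[use] + 0.5))
    if (tRep >= tObs) exceed <- exceed + 1L
  }
  exceed / length(pick)
}

#' Run posterior predictive checks for every species
#'
#' @inheritParams ppcPearson
#' @return the \linkS4class{PosteriorResult} with its \code{ppc} slot filled.
#' @export
addPpc <- function(fit, data, nRep = NULL) {
  pv <- vapply(speciesNames(fit@graph), function(s)
    ppcPearson(fit, data, s, nRep), 0)
  fit@ppc <- pv
  fit
}

## ---- PosteriorResult methods ----------------------------------------------

#' @rdname draws
#' @export
setMethod("draws", "PosteriorResult", function(object, combine = FALSE) {
  if (combine) do.call(rbind, object@draws) else object@draws
})

#' @rdname posteriorSummary
#' @export
setMethod("posteriorSummary", "PosteriorResult",
          function(object) object@summaries)

#' @rdname isConverged
#' @export
setMethod("isConverged", "PosteriorResult", function(object) object@converged)

setMethod("show", "PosteriorResult", function(object) {
  cat("PosteriorResult:", length(object@draws), "chain(s),",
      nrow(object@draws[[1]]), "retained draws each\n")
  conv <- object@converged
  cat("  converged (all R-hat upper CI < 1.1):",
      if (is.na(conv)) "unavailable (single chain)" else conv, "\n")
  s <- object@summaries
  s[, -1] <- round(s[, -1], 3)
  print(s, row.names = FALSE)
  if (length(object@ppc)) {
    cat("  PPC Bayesian p-values:\n")
    print(round(object@ppc, 3))
  }
})
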