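## MCMC front end: configuration, initialization, chain management, and the
## assembly of PosteriorResult objects from the compiled engine.

#' MCMC configuration
#'
#' Defaults are the desk-scale preset (3 chains x 6,000 iterations, burn-in
#' 1,000, thin 5, giving 1,000 retained draws per chain); \code{preset =
#' "paper"} switches to the full-replication scale (3 chains x 50,000,
#' burn-in 5,000, thin 27, ~5,000 retained draws in total).
#'
#' @param nChains number of chains.
#' @param nIterations iterations per chain.
#' @param burnIn burn-in iterations (adaptation happens only here).
#' @param thin thinning interval for retained draws.
#' @param seed base seed; chain c uses \code{seed + c}.
#' @param nMax truncation bound of the latent abundance support; the full
#'   conditional is normalized over 0..nMax by explicit summation.
#' @param adaptInterval Robbins-Monro adaptation batch length.
#' @param targetAccept target acceptance rate of the random-walk updates.
#' @param initScale initial random-walk proposal sd.
#' @param preset \code{"desk"} (default) or \code{"paper"}.
#' @return a validated list of class \code{McmcConfig}.
#' @export
mcmcConfig <- function(nChains = 3L, nIterations = 6000L, burnIn = 1000L,
                       thin = 5L, seed = 1L, nMax = 30L,
                       adaptInterval = 50L, targetAccept = 0.44,
                       initScale = 0.1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    if (preset == "paper") {
      nIterations <- 50000L; burnIn <- 5000L; thin <- 27L
    }
  }
  cfg <- list(nChains = as.integer(nChains),
              nIterations = as.integer(nIterations),
              burnIn = as.integer(burnIn), thin = as.integer(thin),
              seed = as.integer(seed), nMax = as.integer(nMax),
              adaptInterval = as.integer(adaptInterval),
              targetAccept = targetAccept, initScale = initScale)
  stopifnot(cfg$nChains >= 1L, cfg$nIterations >= 1L, cfg$burnIn >= 0L,
            cfg$thin >= 1L, cfg$nMax >= 1L, cfg$adaptInterval >= 1L,
            cfg$targetAccept > 0, cfg$targetAccept < 1)
  if ((cfg$nIterations - cfg$burnIn) / cfg$thin < 100)
    stop("configuration error: fewer than 100 retained draws per chain")
  class(cfg) <- "McmcConfig"
  cfg
}

## Per-species design matrices, in the exact column order of the parameter
## index: intercept, covariates, year dummies.
.designMatrix <- function(sp, sub, data, graph) {
  covs <- if (sub == "state") sp@stateFormula else sp@detectionFormula
  I <- data@design@nSites
  X <- matrix(1, I, 1)
  for (cv in covs) {
    if (!cv %in% names(data@covariates))
      stop("configuration error: covariate '", cv, "' not in data")
    X <- cbind(X, data@covariates[[cv]])
  }
  if (graph@yearEffects) {
    yi <- data@design@yearIndex
    if (!length(yi))
      stop("configuration error: year effects require a design yearIndex")
    for (lev in 2:graph@nYears) X <- cbind(X, as.numeric(yi == lev))
  }
  X
}

## Flatten graph + data into the list the compiled engine consumes.
.enginePayload <- function(graph, data, nMax) {
  pidx <- graph@parameterIndex
  pnames <- pidx$name
  pos <- function(nm) match(nm, pnames) - 1L
  spn <- speciesNames(graph)
  K <- data@design@nSubsamples

  parSp <- match(pidx$species, spn) - 1L
  parSub <- ifelse(pidx$submodel == "state", 0L, 1L)

  species <- lapply(seq_along(graph@species), function(k) {
    sp <- graph@species[[k]]
    y <- data@y[[sp@name]]
    if (is.null(y)) stop("data error: no detections for species ", sp@name)
    storage.mode(y) <- "integer"
    if (sp@stateVariable == "occupancy") y <- pmin(y, 1L)
    idxOf <- function(sub, kinds) {
      sel <- pidx$species == sp@name & pidx$submodel == sub &
        pidx$kind %in% kinds
      pos(pidx$name[sel])
    }
    edges <- function(sub) {
      tgt <- if (sub == "state") "state" else "detection"
      out <- list()
      for (e in sp@interactions) {
        if (e@targetSubmodel != tgt) next
        g0 <- pos(.gammaBaseName(sp@name, sub, e@source))
        g1 <- -1L
        mod <- numeric(0)
        if (!is.na(e@modifier)) {
          g1 <- pos(paste0(sp@name, "_", sub, "_gamma1_", e@source, "_x_",
                           e@modifier))
          if (!e@modifier %in% names(data@covariates))
            stop("configuration error: modifier covariate '", e@modifier,
                 "' not in data")
          mod <- data@covariates[[e@modifier]]
        }
        out[[length(out) + 1L]] <- list(src = match(e@source, spn) - 1L,
                                        g0 = g0, g1 = g1, mod = mod)
      }
      out
    }
    list(state_var = if (sp@stateVariable == "abundance") 0L else 1L,
         y = y, K = K,
         Xs = .designMatrix(sp, "state", data, graph),
         Xd = .designMatrix(sp, "det", data, graph),
         is = idxOf("state", c("intercept", "covariate", "year")),
         id = idxOf("det", c("intercept", "covariate", "year")),
         se = edges("state"), de = edges("det"))
  })

  list(I = data@design@nSites, J = data@design@nOccasions,
       Nmax = as.integer(nMax), occmed = graph@occupancyMediated,
       species = species, par_sp = parSp, par_sub = parSub)
}

.priorVectors <- function(pidx, priors) {
  P <- nrow(pidx)
  pm <- rep(0, P); psd <- rep(2.5, P)
  if (!is.null(priors)) {
    if (!is.null(priors$mean)) pm <- rep_len(unlist(priors$mean), P)
    if (!is.null(priors$sd)) psd <- rep_len(unlist(priors$sd), P)
    if (!is.null(priors$parameters)) {
      for (nm in names(priors$parameters)) {
        k <- match(nm, pidx$name)
        if (is.na(k)) stop("configuration error: unknown prior target ", nm)
        pr <- priors$parameters[[nm]]
        if (!is.null(pr$mean)) pm[k] <- pr$mean
        if (!is.null(pr$sd)) psd[k] <- pr$sd
      }
    }
  }
  list(mean = pm, sd = psd)
}

## Structurally valid, overdispersed chain initialization: N starts at the
## detection indicator plus Poisson(1) jitter, z at the detection indicator,
## coefficients at standard-Normal draws.
.initChain <- function(graph, data, payload) {
  I <- payload$I
  S <- length(graph@species)
  lat <- matrix(0L, I, S)
  for (k in seq_len(S)) {
    y <- payload$species[[k]]$y
    detected <- as.integer(rowSums(y > 0, na.rm = TRUE) > 0)
    if (payload$species[[k]]$state_var == 0L)
      lat[, k] <- pmin(detected + stats::rpois(I, 1), payload$Nmax)
    else
      lat[, k] <- detected
  }
  theta0 <- stats::rnorm(nrow(graph@parameterIndex), 0, 1)
  list(latent = lat, theta0 = theta0)
}

#' Run one MCMC chain
#'
#' One systematic-sweep chain: every latent abundance is refreshed by an
#' exact categorical Gibbs draw over \code{0..nMax} (its full conditional,
#' including downstream-likelihood contributions), every latent occupancy
#' state by its closed-form Bernoulli conditional, then every coefficient by
#' an adaptive random-walk Metropolis step. Reproducible given
#' \code{(mcmc$seed, chainId)}.
#'
#' @param graph a \linkS4class{ModelGraph}.
#' @param data a \linkS4class{DetectionData}.
#' @param mcmc a \code{\link{mcmcConfig}}.
#' @param chainId chain number (seeds the RNG as \code{seed + chainId}).
#' @param priors optional prior override list: \code{mean}, \code{sd}
#'   (scalars) and/or \code{parameters} (named per-parameter overrides).
#'   Default: independent Normal(0, 2.5) on every coefficient.
#' @param saveLatent record thinned latent-state draws.
#' @param fixCoefficients hold coefficients at their initial values and only
#'   update latent states (used by the full-conditional oracle checks).
#' @param theta0 optional fixed coefficient start values (named or in
#'   parameter-index order).
#' @return list with elements \code{draws} (matrix, named columns),
#'   \code{latent} (matrix of latent draws or NULL), \code{acceptRate},
#'   \code{proposalScales}, \code{truncationWarnings}.
#' @export
runChain <- function(graph, data, mcmc = mcmcConfig(), chainId = 1L,
                     priors = NULL, saveLatent = FALSE,
                     fixCoefficients = FALSE, theta0 = NULL) {
  payload <- .enginePayload(graph, data, mcmc$nMax)
  pidx <- graph@parameterIndex
  set.seed(mcmc$seed + chainId)
  ini <- .initChain(graph, data, payload)
  if (!is.null(theta0)) {
    if (!is.null(names(theta0))) theta0 <- theta0[pidx$name]
    if (anyNA(theta0)) stop("theta0 must cover every parameter")
    ini$theta0 <- unname(theta0)
  }
  pr <- .priorVectors(pidx, priors)
  payload$theta0 <- ini$theta0
  payload$prior_mean <- pr$mean
  payload$prior_sd <- pr$sd
  payload$init_latent <- ini$latent

  res <- .runChainCpp(payload, mcmc$nIterations, mcmc$burnIn, mcmc$thin,
                      mcmc$adaptInterval, mcmc$targetAccept, mcmc$initScale,
                      fixCoefficients, saveLatent)
  colnames(res$draws) <- pidx$name
  names(res$accept_rate) <- pidx$name
  list(draws = res$draws, latent = res$latent,
       finalLatent = res$final_latent,
       acceptRate = res$accept_rate,
       proposalScales = res$proposal_scales,
       truncationWarnings = res$trunc_warn)
}

#' Fit an abundance-mediated interaction model
#'
#' Runs \code{mcmc$nChains} chains (chain c seeded with \code{seed + c}),
#' assembles the retained draws, and attaches posterior summaries (histogram
#' posterior mode, mean, sd, equal-tailed 95\% credible interval),
#' Gelman-Rubin diagnostics with their upper confidence limits, and effective
#' sample sizes.
#'
#' @inheritParams runChain
#' @param saveLatent record thinned latent-state draws (needed by
#'   \code{\link{ppcPearson}}).
#' @return a \linkS4class{PosteriorResult}.
#' @examples
#' \donttest{
#' sc <- presetStudy2(I = 60, J = 4)
#' sim <- simulateDataset(sc)
#' fit <- fitModel(sc@graph, sim$data,
#'                 mcmcConfig(nIterations = 600, burnIn = 100, thin = 1))
#' posteriorSummary(fit)
#' }
#' @export
fitModel <- function(graph, data, mcmc = mcmcConfig(), priors = NULL,
                     saveLatent = FALSE) {
  ## latent support must leave room above the observed evidence of presence
  anyDet <- any(vapply(names(data@y), function(nm) {
    sp <- graph@species[[match(nm, speciesNames(graph))]]
    sp@stateVariable == "abundance" && any(data@y[[nm]] > 0, na.rm = TRUE)
  }, TRUE))
  if (anyDet && mcmc$nMax < 2L)
    stop("configuration error: nMax must exceed the observed evidence of presence")

  chains <- vector("list", mcmc$nChains)
  failures <- character(0)
  for (cc in seq_len(mcmc$nChains)) {
    chains[[cc]] <- tryCatch(
      runChain(graph, data, mcmc, chainId = cc, priors = priors,
               saveLatent = saveLatent),
      error = function(e) e)
    if (inherits(chains[[cc]], "error")) {
      failures <- c(failures, paste0("chain ", cc, ": ",
                                     conditionMessage(chains[[cc]])))
      chains[[cc]] <- NULL
    }
  }
  ok <- !vapply(chains, is.null, TRUE)
  if (!any(ok)) stop("all chains failed: ", paste(failures, collapse = "; "))
  if (length(failures))
    warning("partial result, flagged unusable: ",
            paste(failures, collapse = "; "))
  chains <- chains[ok]

  drawList <- lapply(chains, `[[`, "draws")
  latList <- lapply(chains, `[[`, "latent")
  if (!saveLatent) latList <- list()
  pnames <- graph@parameterIndex$name

  rh <- gelmanRubin(drawList)
  allDraws <- do.call(rbind, drawList)
  summ <- data.frame(
    parameter = pnames,
    mode = apply(allDraws, 2, posteriorMode),
    mean = colMeans(allDraws),
    sd = apply(allDraws, 2, stats::sd),
    lo95 = apply(allDraws, 2, function(x) equalTailedCri(x)[1]),
    hi95 = apply(allDraws, 2, function(x) equalTailedCri(x)[2]),
    rhat = rh$point, rhatUpper = rh$upper,
    ess = effectiveSizeDraws(drawList),
    row.names = NULL)

  conv <- if (length(drawList) < 2L || length(failures)) NA
          else all(rh$upper < 1.1)
  if (length(failures)) conv <- FALSE

  tw <- sum(vapply(chains, `[[`, 0L, "truncationWarnings"))
  if (tw > 0)
    warning("latent-abundance truncation: P(N = nMax) exceeded 1e-6 in ", tw,
            " updates; consider raising nMax")

  new("PosteriorResult",
      draws = drawList, parameters = pnames, summaries = summ,
      rhat = data.frame(parameter = pnames, point = rh$point,
                        upper = rh$upper, row.names = NULL),
      converged = conv, ppc = numeric(0), latent = latList,
      mcmc = list(config = unclass(mcmc),
                  chainSeeds = mcmc$seed + seq_len(mcmc$nChains),
                  failures = failures,
                  acceptRate = lapply(chains, `[[`, "acceptRate"),
                  truncationWarnings = tw),
      graph = graph)
}

#' Gibbs update of one latent abundance (single-site operation)
#'
#' Draws N from its exact full conditional over \code{0..nMax} (explicitly
#' normalized), as the sampler does internally. Exposed for inspection and
#' testing; \code{\link{latentAbundancePmf}} returns the distribution itself.
#'
#' @inheritParams latentAbundancePmf
#' @return updated value of N.
#' @export
updateLatentAbundance <- function(site, species, states, coefs, data, graph,
                                  nMax = 30L) {
  pmf <- latentAbundancePmf(site, species, states, coefs, data, graph, nMax)
  sample(0:nMax, 1L, prob = pmf)
}

#' Gibbs update of one latent occupancy state (single-site operation)
#'
#' Forced to 1 by any detection; otherwise a Bernoulli draw from the
#' closed-form conditional.
#'
#' @inheritParams latentOccupancyProb
#' @return updated value of z.
#' @export
updateLatentOccupancy <- function(site, species, states, coefs, data, graph) {
  yrow <- data@y[[species]][site, ]
  if (any(yrow > 0, na.rm = TRUE)) return(1L)
  as.integer(stats::runif(1) <
             latentOccupancyProb(site, species, states, coefs, data, graph))
}
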