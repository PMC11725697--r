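## Likelihood components of the abundance-mediated interaction model, as pure
## R functions. The C++ sampler reimplements these incrementally for speed;
## the functions here define the model and serve as the reference route in the
## full-conditional oracle tests.

.PROB_FLOOR <- 1e-12

.clampProb <- function(p) pmin(pmax(p, .PROB_FLOOR), 1 - .PROB_FLOOR)

#' Royle-Nichols site-level detection probability
#'
#' Probability that one or more of the \code{N} individuals present is
#' detected, given individual detection probability \code{r}:
#' \eqn{p = 1 - (1 - r)^N}. Zero when \code{N = 0}; nondecreasing in both
#' arguments.
#'
#' @param r individual detection probability in [0, 1].
#' @param N non-negative integer abundance.
#' @return detection probability (vectorized).
#' @examples
#' rnDetectionProb(0.3, 2)  # 1 - 0.7^2 = 0.51
#' @export
rnDetectionProb <- function(r, N) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  if (any(N < 0)) stop("N must be non-negative")
  1 - (1 - r)^N
}

#' Binomial observation log-density
#'
#' Log-density of a count of detections \code{y} out of \code{K} subsamples
#' with site-level detection probability \code{p}. Structural zeros are
#' exact: \code{-Inf} when \code{p = 0} and \code{y > 0} (and when
#' \code{p = 1} and \code{y < K}); otherwise \code{p} is clamped away from
#' {0, 1} by 1e-12 for numerical stability.
#'
#' @param y observed count, 0..K.
#' @param K number of subsamples (binomial trials).
#' @param p detection probability.
#' @export
binomObsLoglik <- function(y, K, p) {
  if (any(y < 0) || any(y > K)) stop("data error: y must lie in 0..K")
  n <- max(length(y), length(K), length(p))
  y <- rep_len(y, n); K <- rep_len(K, n); p <- rep_len(p, n)
  out <- numeric(n)
  z0 <- p == 0
  z1 <- p == 1
  out[z0] <- ifelse(y[z0] > 0, -Inf, 0)
  out[z1] <- ifelse(y[z1] < K[z1], -Inf, 0)
  mid <- !z0 & !z1
  out[mid] <- stats::dbinom(y[mid], K[mid], .clampProb(p[mid]), log = TRUE)
  out
}

#' Bernoulli observation log-density conditional on presence
#'
#' \eqn{y \sim Bernoulli(p z)}: detection is impossible at an unoccupied
#' site (no false positives), so the result is exactly \code{-Inf} when
#' \code{z = 0} and \code{y = 1}.
#'
#' @param y observed detection, 0 or 1.
#' @param p detection probability given presence.
#' @param z latent occupancy state, 0 or 1.
#' @export
bernoulliObsLoglik <- function(y, p, z) {
  if (any(!y %in% c(0, 1)) || any(!z %in% c(0, 1)))
    stop("y and z must be binary")
  n <- max(length(y), length(p), length(z))
  y <- rep_len(y, n); p <- rep_len(p, n); z <- rep_len(z, n)
  out <- numeric(n)
  absent <- z == 0
  out[absent] <- ifelse(y[absent] == 1, -Inf, 0)
  pc <- .clampProb(p[!absent])
  out[!absent] <- ifelse(y[!absent] == 1, log(pc), log1p(-pc))
  out
}

#' Linear predictor with abundance-mediated interaction terms
#'
#' Assembles \eqn{\eta = \beta_0 + \sum \beta x + \sum_{edges} [\gamma_0 f(N_{src})
#' + \gamma_1 f(N_{src}) x_{mod}]} for one species' state or detection
#' submodel at one site, where \eqn{f} is the identity or, in the
#' occupancy-mediated comparison variant, the indicator \eqn{1\{N_{src}>0\}}.
#' Year-specific intercepts (dummy coding) are added when the graph carries
#' year effects.
#'
#' @param graph a \linkS4class{ModelGraph}.
#' @param species species name.
#' @param submodel \code{"state"} or \code{"det"}.
#' @param covariates named numeric of this site's covariate values.
#' @param coefs named numeric of all model coefficients.
#' @param states named numeric of latent states of all species at this site
#'   (N for abundance-state species, z for occupancy-state species).
#' @param yearLevel this site's 1-based year level (NA when no year effects).
#' @return the linear predictor (link scale).
#' @examples
#' cfg <- list(species = list(
#'   list(name = "D", role = "dominant", state = "abundance"),
#'   list(name = "S", role = "subordinate", state = "occupancy",
#'        interactions = list(list(source = "D", target = "state")))))
#' g <- buildModelGraph(cfg)
#' coefs <- c(D_state_int = 0, D_det_int = 0,
#'            S_state_int = 0, S_state_gamma0_D = -1, S_det_int = 0)
#' linearPredictor(g, "S", "state", numeric(0), coefs, c(D = 2, S = 1))
#' @export
linearPredictor <- function(graph, species, submodel, covariates, coefs,
                            states = numeric(0), yearLevel = NA_integer_) {
  pidx <- graph@parameterIndex
  rows <- pidx[pidx$species == species & pidx$submodel == submodel, ,
               drop = FALSE]
  if (!nrow(rows)) stop("configuration error: unknown species/submodel")
  eta <- 0
  for (k in seq_len(nrow(rows))) {
    nm <- rows$name[k]
    if (!nm %in% names(coefs))
      stop("configuration error: coefficient '", nm, "' not supplied")
    b <- coefs[[nm]]
    eta <- eta + switch(rows$kind[k],
      intercept = b,
      covariate = {
        cv <- rows$covariate[k]
        if (!cv %in% names(covariates))
          stop("configuration error: covariate '", cv, "' missing")
        b * covariates[[cv]]
      },
      year = {
        lev <- as.integer(sub("^yr", "", sub(".*_yr", "yr", nm)))
        if (!is.na(yearLevel) && yearLevel == lev) b else 0
      },
      gamma0 = ,
      gamma1 = {
        src <- rows$source[k]
        if (!src %in% names(states))
          stop("configuration error: upstream state for '", src, "' missing")
        f <- if (graph@occupancyMediated) as.numeric(states[[src]] > 0)
             else states[[src]]
        if (rows$kind[k] == "gamma0") b * f
        else {
          cv <- rows$covariate[k]
          if (!cv %in% names(covariates))
            stop("configuration error: modifier covariate '", cv, "' missing")
          b * f * covariates[[cv]]
        }
      })
  }
  unname(eta)
}

## Covariate row for one site as a named numeric vector.
.siteCovariates <- function(data, site) {
  cv <- data@covariates
  if (!nrow(cv)) return(numeric(0))
  out <- as.numeric(cv[site, , drop = TRUE])
  names(out) <- names(cv)
  out
}

.siteYear <- function(data, site) {
  if (length(data@design@yearIndex)) data@design@yearIndex[site]
  else NA_integer_
}

#' Joint log-density of one site
#'
#' Sum of every state term (Poisson for abundance species, Bernoulli for
#' occupancy species) and every unmasked occasion-level observation term at
#' one site, given complete latent states and coefficients. Masked occasions
#' contribute exactly zero.
#'
#' @param site site index (1-based).
#' @param states named numeric of latent states at this site.
#' @param coefs named numeric of all coefficients.
#' @param data a \linkS4class{DetectionData}.
#' @param graph a \linkS4class{ModelGraph}.
#' @return the site's joint log-density.
#' @export
siteJointLoglik <- function(site, states, coefs, data, graph) {
  covs <- .siteCovariates(data, site)
  yr <- .siteYear(data, site)
  K <- data@design@nSubsamples
  mask <- data@design@observedMask[site, ]
  ll <- 0
  for (sp in graph@species) {
    etaS <- linearPredictor(graph, sp@name, "state", covs, coefs, states, yr)
    etaD <- linearPredictor(graph, sp@name, "det", covs, coefs, states, yr)
    yrow <- data@y[[sp@name]][site, ]
    use <- mask & !is.na(yrow)
    if (sp@stateVariable == "abundance") {
      N <- states[[sp@name]]
      ll <- ll + stats::dpois(N, exp(etaS), log = TRUE)
      if (any(use)) {
        p <- rnDetectionProb(stats::plogis(etaD), N)
        ll <- ll + sum(binomObsLoglik(yrow[use], K, p))
      }
    } else {
      z <- states[[sp@name]]
      psi <- .clampProb(stats::plogis(etaS))
      ll <- ll + ifelse(z > 0, log(psi), log1p(-psi))
      if (any(use)) {
        p <- stats::plogis(etaD)
        ll <- ll + sum(bernoulliObsLoglik(yrow[use], p, z))
      }
    }
  }
  ll
}

#' Brute-force full conditional of a latent abundance
#'
#' Normalizes the joint site density over \code{N = 0..nMax} by explicit
#' summation, holding everything else fixed. This is the reference against
#' which the sampler's Gibbs update is checked.
#'
#' @inheritParams siteJointLoglik
#' @param species an abundance-state species name.
#' @param nMax truncation bound of the latent support.
#' @return numeric vector of probabilities over 0..nMax.
#' @export
latentAbundancePmf <- function(site, species, states, coefs, data, graph,
                               nMax = 30L) {
  logw <- vapply(0:nMax, function(n) {
    st <- states; st[[species]] <- n
    siteJointLoglik(site, st, coefs, data, graph)
  }, 0)
  m <- max(logw)
  if (!is.finite(m)) stop("sampler error: no support mass at site ", site)
  w <- exp(logw - m)
  w / sum(w)
}

#' Brute-force full conditional of a latent occupancy state
#'
#' @inheritParams latentAbundancePmf
#' @param species an occupancy-state species name.
#' @return P(z = 1 | everything else).
#' @export
latentOccupancyProb <- function(site, species, states, coefs, data, graph) {
  lw <- vapply(0:1, function(z) {
    st <- states; st[[species]] <- z
    siteJointLoglik(site, st, coefs, data, graph)
  }, 0)
  m <- max(lw)
  w <- exp(lw - m)
  w[2] / sum(w)
}
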