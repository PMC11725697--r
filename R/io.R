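## Tabular data contracts and run manifests. Site and occasion indices are
## 1-based in files (ecology convention). Counts are stored per occasion,
## already aggregated over the K subsamples; masked cells are simply absent
## rows, never zeros.

#' Read one species' detection matrix from CSV
#'
#' Expects columns \code{site}, \code{occasion}, \code{y}, \code{K}. Cells
#' with no row are masked (NA). Counts above K and duplicate (site, occasion)
#' pairs are data errors.
#'
#' @param path CSV file path.
#' @param design the \linkS4class{StudyDesign} the file must conform to.
#' @return integer nSites x nOccasions matrix with NA in masked cells.
#' @export
readDetectionCsv <- function(path, design) {
  df <- utils::read.csv(path)
  need <- c("site", "occasion", "y", "K")
  if (!all(need %in% names(df)))
    stop("data error: ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (any(df$K != design@nSubsamples))
    stop("data error: K column disagrees with the design (K = ",
         design@nSubsamples, ")")
  dup <- duplicated(df[, c("site", "occasion")])
  if (any(dup))
    stop("data error: duplicate (site, occasion) at row ", which(dup)[1])
  bad <- df$y > df$K | df$y < 0
  if (any(bad))
    stop("data error: y outside 0..K at row ", which(bad)[1],
         " (site ", df$site[which(bad)[1]], ")")
  if (any(df$site < 1 | df$site > design@nSites) ||
      any(df$occasion < 1 | df$occasion > design@nOccasions))
    stop("data error: site/occasion index outside the design")
  y <- matrix(NA_integer_, design@nSites, design@nOccasions)
  y[cbind(df$site, df$occasion)] <- as.integer(df$y)
  y
}

#' Write / read a simulated dataset directory
#'
#' Writes \code{detections_<species>.csv} (site, occasion, y, K; unmasked
#' cells only), \code{covariates.csv} (site, name, value), \code{mask.csv}
#' (site, occasion, observed), \code{design.json} and \code{truth.json}.
#' \code{readDataset} reconstructs the \linkS4class{DetectionData} and truth
#' exactly (write-read round trip is the identity).
#'
#' @param sim list with \code{data} and optional \code{truth}, as returned by
#'   \code{\link{simulateDataset}} (a bare \linkS4class{DetectionData} is
#'   also accepted).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  if (is(sim, "DetectionData")) sim <- list(data = sim)
  data <- sim$data
  d <- data@design
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(data@y)) {
    y <- data@y[[nm]]
    idx <- which(!is.na(y), arr.ind = TRUE)
    df <- data.frame(site = idx[, 1], occasion = idx[, 2],
                     y = y[idx], K = d@nSubsamples)
    df <- df[order(df$site, df$occasion), ]
    utils::write.csv(df, file.path(dir, paste0("detections_", nm, ".csv")),
                     row.names = FALSE)
  }
  cv <- data@covariates
  cvdf <- if (ncol(cv)) do.call(rbind, lapply(names(cv), function(nm)
    data.frame(site = seq_len(d@nSites), name = nm, value = cv[[nm]])))
    else data.frame(site = integer(0), name = character(0),
                    value = numeric(0))
  utils::write.csv(cvdf, file.path(dir, "covariates.csv"), row.names = FALSE)
  mk <- data@design@observedMask
  utils::write.csv(
    data.frame(site = rep(seq_len(d@nSites), ncol(mk)),
               occasion = rep(seq_len(ncol(mk)), each = d@nSites),
               observed = as.vector(mk)),
    file.path(dir, "mask.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_sites = d@nSites, n_occasions = d@nOccasions,
         n_subsamples = d@nSubsamples,
         year_index = if (length(d@yearIndex)) d@yearIndex else NULL,
         site_ids = data@siteIds, species = names(data@y)),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$truth))
    jsonlite::write_json(
      list(values = as.list(sim$truth$values)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  ds <- jsonlite::read_json(file.path(dir, "design.json"),
                            simplifyVector = TRUE)
  mk <- utils::read.csv(file.path(dir, "mask.csv"))
  mask <- matrix(TRUE, ds$n_sites, ds$n_occasions)
  mask[cbind(mk$site, mk$occasion)] <- mk$observed
  design <- studyDesign(ds$n_sites, ds$n_occasions, ds$n_subsamples,
                        yearIndex = ds$year_index %||% integer(0),
                        observedMask = mask, allowEmptySites = TRUE)
  y <- lapply(ds$species, function(nm)
    readDetectionCsv(file.path(dir, paste0("detections_", nm, ".csv")),
                     design))
  names(y) <- ds$species
  cvdf <- utils::read.csv(file.path(dir, "covariates.csv"))
  covs <- if (nrow(cvdf)) {
    out <- as.data.frame(lapply(split(cvdf, cvdf$name), function(b)
      b$value[order(b$site)]))
    out[, unique(cvdf$name), drop = FALSE]
  } else data.frame(row.names = seq_len(ds$n_sites))
  data <- new("DetectionData", y = y, design = design, covariates = covs,
              siteIds = as.character(ds$site_ids))
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth <- list(values = unlist(tj$values))
  }
  list(data = data, truth = truth)
}

#' Write posterior chains, summary table and run manifest
#'
#' \code{chains.csv} is tidy (chain, iteration, parameter, value);
#' \code{summary.csv} has one row per parameter (mode, mean, sd, lo95, hi95,
#' rhat, rhat_upper, ess); \code{manifest.json} records the configuration,
#' seeds and versions needed to reproduce the run.
#'
#' @param fit a \linkS4class{PosteriorResult}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeFit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(fit@draws), function(cc) {
    m <- fit@draws[[cc]]
    data.frame(chain = cc,
               iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "chains.csv"),
                   row.names = FALSE)
  s <- fit@summaries
  names(s) <- c("parameter", "mode", "mean", "sd", "lo95", "hi95",
                "rhat", "rhat_upper", "ess")
  utils::write.csv(s, file.path(dir, "summary.csv"), row.names = FALSE)
  writeManifest(file.path(dir, "manifest.json"),
                list(mcmc = fit@mcmc$config, chain_seeds = fit@mcmc$chainSeeds,
                     converged = fit@converged,
                     model = graphToConfig(fit@graph)))
  invisible(dir)
}

#' Read tidy chains back into per-chain matrices
#'
#' @param path chains.csv written by \code{\link{writeFit}}.
#' @return list of per-chain draw matrices.
#' @export
readChainsCsv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$chain), function(b) {
    pars <- unique(b$parameter)
    m <- vapply(pars, function(p) b$value[b$parameter == p],
                numeric(sum(b$parameter == pars[1])))
    colnames(m) <- pars
    m
  })
}

#' Write study harness outputs
#'
#' @param study result of \code{\link{runStudy}}.
#' @param dir output directory; writes \code{study_results.csv},
#'   \code{study_summary.csv} and \code{manifest.json}.
#' @param meta extra fields for the manifest (e.g. scenario description and
#'   seeds).
#' @return \code{dir}, invisibly.
#' @export
writeStudyResults <- function(study, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$results, file.path(dir, "study_results.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "study_summary.csv"),
                   row.names = FALSE)
  writeManifest(file.path(dir, "manifest.json"),
                c(meta, list(truths = as.list(study$truths))))
  invisible(dir)
}

#' Write a reproducibility manifest
#'
#' @param path output JSON path.
#' @param fields named list of run settings (configs, seeds); versions and a
#'   timestamp are added.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, fields = list()) {
  fields$versions <- list(
    R = as.character(getRversion()),
    amim = as.character(utils::packageVersion("amim")))
  fields$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
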