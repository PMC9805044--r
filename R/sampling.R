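## Observation design: annual random draws of grid cells carrying both
## the operating-model truth and the generating ESM's covariates.

#' Draw random annual samples from a truth field
#'
#' Samples \code{nPerYear} cells uniformly without replacement within
#' each year over the archetype's domain, independently across years,
#' and joins the operating-model truth (presence, biomass) with the
#' environmental covariates of the same forcing that generated it.
#' The default design (500 cells/year) gives 13,000 training rows over
#' 1985--2010 and 45,000 test rows over 2011--2100.
#'
#' @param truth a \linkS4class{TruthField}.
#' @param env the \linkS4class{EnvField} that generated it.
#' @param years years to sample.
#' @param nPerYear cells per year; if it exceeds the domain size every
#'   cell is taken once and a warning is issued.
#' @param seed integer seed.
#' @param role "train" or "test".
#' @return A \linkS4class{SampleSet}; its SDM-facing covariates are the
#'   truth drivers until [attachProxyCovariates()] substitutes the
#'   chlorophyll proxy.
#' @export
sampleCells <- function(truth, env, years, nPerYear = 500, seed = 1L,
                        role = c("train", "test")) {
  role <- match.arg(role)
  stopifnot(is(truth, "TruthField"), is(env, "EnvField"))
  years <- as.integer(years)
  ty <- envYears(truth)
  stopIfNot(all(years %in% ty), "requested years outside truth range")
  stopIfNot(nPerYear >= 1, "nPerYear must be >= 1")
  g <- gridTable(env)
  domain <- which(metadata(truth)$domainMask)
  if (nPerYear > length(domain)) {
    warning("nPerYear exceeds domain size (", length(domain),
            "); sampling every cell once per year")
  }
  n <- min(nPerYear, length(domain))

  set.seed(childSeed(seed, "sample", role, metadata(truth)$archetype,
                     esmId(env)))
  pres <- assay(truth, "presence"); biom <- assay(truth, "biomass")
  vars <- envVariables(env)
  va <- lapply(setNames(vars, vars), function(v) assay(env, v))
  rows <- lapply(years, function(yr) {
    j <- match(yr, ty)
    cells <- sort(sample(domain, n, replace = FALSE))
    df <- data.frame(year = yr, cell = cells,
                     lat = g$lat[cells], lon = g$lon[cells],
                     bathymetry = g$bathymetry[cells])
    for (v in vars) df[[v]] <- va[[v]][cells, j]
    df$presence <- pres[cells, j]
    df$biomass <- biom[cells, j]
    df
  })
  dat <- do.call(rbind, rows)
  rownames(dat) <- NULL

  spec <- metadata(truth)$spec
  drivers <- vapply(spec@curves, function(cv) cv@variable, "")
  new("SampleSet", data = dat, role = role,
      archetype = metadata(truth)$archetype, esmId = esmId(env),
      sdmCovariates = drivers, seed = as.integer(seed))
}

#' Substitute the chlorophyll prey proxy into the SDM covariate set
#'
#' The estimation models never see the true zooplankton prey fields;
#' chlorophyll-a stands in as an imperfect proxy, emulating real-world
#' conditions where prey information is unavailable.  This replaces any
#' ZOO50/ZOO200 covariate in the SDM-facing covariate list with CHL
#' (truth columns are untouched); archetypes without zooplankton drivers
#' are returned unchanged.  Idempotent.
#'
#' @param samples a \linkS4class{SampleSet}.
#' @return The \linkS4class{SampleSet} with updated
#'   \code{sdmCovariates}.
#' @export
attachProxyCovariates <- function(samples) {
  stopifnot(is(samples, "SampleSet"))
  cov <- samples@sdmCovariates
  if (any(cov %in% c("ZOO50", "ZOO200"))) {
    if (!"CHL" %in% names(samples@data))
      stop("CHL missing from samples; cannot attach prey proxy",
           call. = FALSE)
    cov[cov %in% c("ZOO50", "ZOO200")] <- "CHL"
    cov <- unique(cov)
  }
  samples@sdmCovariates <- cov
  samples
}
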