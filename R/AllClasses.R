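#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

## ---------------------------------------------------------------------------
## Grid geometry
## ---------------------------------------------------------------------------

#' GridSpec: rectangular study-domain geometry
#'
#' Describes a regular lat/lon grid (cell centers) and the simulation
#' year axis.  The default emulates a California Current-like domain,
#' 30--48 degrees N and from the coast westward to -134 degrees E, at a
#' configurable resolution (0.5 degrees by default).
#'
#' @slot latMin,latMax southern / northern domain edges (degrees N).
#' @slot lonMin,lonMax western / eastern domain edges (degrees E,
#'   negative west).  The eastern edge plays the role of the coastline.
#' @slot resolution cell size in degrees.
#' @slot years integer vector of simulation years (inclusive).
#' @export
setClass("GridSpec",
  slots = c(latMin = "numeric", latMax = "numeric",
            lonMin = "numeric", lonMax = "numeric",
            resolution = "numeric", years = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@resolution) != 1 || !is.finite(object@resolution) ||
        object@resolution <= 0)
      msg <- c(msg, "resolution must be a single positive number")
    if (object@latMin >= object@latMax) msg <- c(msg, "latMin must be < latMax")
    if (object@lonMin >= object@lonMax) msg <- c(msg, "lonMin must be < lonMax")
    if (length(object@years) < 1 || anyNA(object@years))
      msg <- c(msg, "years must be a non-empty integer vector")
    if (length(msg)) msg else TRUE
  })

#' Construct a GridSpec
#'
#' @param latMin,latMax,lonMin,lonMax domain edges in degrees.
#' @param resolution cell size in degrees (> 0).
#' @param years integer vector of simulation years.
#' @return A \linkS4class{GridSpec}.
#' @examples
#' gridSpec(resolution = 1)
#' @export
gridSpec <- function(latMin = 30, latMax = 48, lonMin = -134, lonMax = -116,
                     resolution = 0.5, years = 1985:2100) {
  new("GridSpec", latMin = latMin, latMax = latMax, lonMin = lonMin,
      lonMax = lonMax, resolution = resolution, years = as.integer(years))
}

## ---------------------------------------------------------------------------
## Pseudo-ESM forcing style
## ---------------------------------------------------------------------------

#' EsmStyle: statistical recipe for one pseudo-ESM
#'
#' A pseudo-ESM is a synthetic earth-system-model realization defined by
#' per-variable linear trends, decadal cycles, and autocorrelated
#' interannual noise on top of a shared climatological base state.  The
#' three default styles diverge in their trends (most strongly for
#' bottom oxygen and zooplankton), with divergence amplified nearshore.
#'
#' @slot esmId label, e.g. "pseudo-GFDL".
#' @slot trendPerDecade named numeric, linear trend per decade in the
#'   variable's own units (positive for SST/BT, negative for MLD/BO/ZOO).
#' @slot cycleAmp named numeric, amplitude of the decadal sinusoid.
#' @slot cyclePeriod period of the decadal cycle in years.
#' @slot cyclePhase phase offset in radians (differs among styles).
#' @slot noiseSd named numeric, interannual noise standard deviation.
#' @slot arPhi AR(1) coefficient of the interannual noise in time.
#' @slot spatialRange Gaussian smoothing range of the noise, in cells.
#' @slot nearshoreAmp multiplicative amplification of the trend at the
#'   coast (decaying offshore); > 1 makes ESMs diverge most nearshore.
#' @export
setClass("EsmStyle",
  slots = c(esmId = "character", trendPerDecade = "numeric",
            cycleAmp = "numeric", cyclePeriod = "numeric",
            cyclePhase = "numeric", noiseSd = "numeric",
            arPhi = "numeric", spatialRange = "numeric",
            nearshoreAmp = "numeric"))

#' Construct an EsmStyle
#'
#' @param esmId character label.
#' @param trendPerDecade,cycleAmp,noiseSd named numeric vectors keyed by
#'   variable name (subset of SST, BT, BO, MLD, ZOO50, ZOO200, CHL);
#'   unnamed variables default to 0.
#' @param cyclePeriod,cyclePhase decadal-cycle period (years) and phase.
#' @param arPhi AR(1) coefficient of interannual noise.
#' @param spatialRange spatial smoothing range of the noise (cells).
#' @param nearshoreAmp nearshore trend amplification factor.
#' @return An \linkS4class{EsmStyle}.
#' @export
esmStyle <- function(esmId, trendPerDecade = numeric(), cycleAmp = numeric(),
                     cyclePeriod = 30, cyclePhase = 0, noiseSd = numeric(),
                     arPhi = 0.5, spatialRange = 2, nearshoreAmp = 1.5) {
  new("EsmStyle", esmId = esmId, trendPerDecade = trendPerDecade,
      cycleAmp = cycleAmp, cyclePeriod = cyclePeriod, cyclePhase = cyclePhase,
      noiseSd = noiseSd, arPhi = arPhi, spatialRange = spatialRange,
      nearshoreAmp = nearshoreAmp)
}

## ---------------------------------------------------------------------------
## Gridded fields: EnvField, TruthField (SummarizedExperiment containers)
## ---------------------------------------------------------------------------

#' EnvField: gridded annual environmental forcing
#'
#' A \linkS4class{SummarizedExperiment} whose assays are environmental
#' variables as (cell x year) matrices; \code{rowData} holds the static
#' cell table (lat, lon, bathymetry, distance from coast), and
#' \code{colData} the year axis.  All values are annual spring
#' (March--May) means.  Metadata carries the pseudo-ESM id.
#'
#' @seealso [generateForcing()], [envVariables()], [esmId()]
#' @export
setClass("EnvField", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    need <- c("lat", "lon", "bathymetry")
    if (!all(need %in% colnames(rowData(object))))
      msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
    if (!"year" %in% colnames(colData(object)))
      msg <- c(msg, "colData must contain 'year'")
    for (v in assayNames(object)) {
      a <- assay(object, v)
      if (anyNA(a)) msg <- c(msg, paste("assay", v, "contains NA"))
      if (v %in% c("BO", "CHL", "ZOO50", "ZOO200") && any(a < 0, na.rm = TRUE))
        msg <- c(msg, paste("assay", v, "must be >= 0"))
      if (v == "MLD" && any(a <= 0, na.rm = TRUE))
        msg <- c(msg, "assay MLD must be > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' TruthField: simulated "observed" species state
#'
#' Operating-model output as a \linkS4class{SummarizedExperiment} with
#' assays \code{suitability}, \code{presence} and \code{biomass} as
#' (cell x year) matrices.  \code{colData} carries the year axis and the
#' annual population multiplier; metadata carries the archetype spec.
#' Biomass is zero exactly where presence is zero (hurdle consistency),
#' and identically zero outside the archetype's domain mask.
#'
#' @seealso [drawTruth()]
#' @export
setClass("TruthField", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    need <- c("suitability", "presence", "biomass")
    if (!all(need %in% assayNames(object)))
      msg <- c(msg, "assays suitability, presence, biomass required")
    else {
      s <- assay(object, "suitability")
      p <- assay(object, "presence")
      b <- assay(object, "biomass")
      if (any(s < 0 | s > 1, na.rm = TRUE))
        msg <- c(msg, "suitability must lie in [0, 1]")
      if (!all(p %in% c(0, 1))) msg <- c(msg, "presence must be 0/1")
      if (any(b < 0)) msg <- c(msg, "biomass must be >= 0")
      if (any((b > 0) != (p == 1)))
        msg <- c(msg, "hurdle violation: biomass > 0 iff presence = 1")
    }
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Response curves and archetypes
## ---------------------------------------------------------------------------

#' ResponseCurve: one species--environment preference curve
#'
#' Maps an environmental variable to habitat suitability in \[0, 1\].
#' Supported forms: \code{gaussian} (optimum, breadth; attains 1 at the
#' optimum), \code{logistic} (midpoint, slope; monotone, 0.5 at the
#' midpoint, increasing when slope > 0), and \code{ramp} (low, high;
#' linear between the two knots, clamped -- decreasing when low > high).
#'
#' @slot variable environmental variable the curve responds to.
#' @slot form one of "gaussian", "logistic", "ramp".
#' @slot params named numeric parameters of the form.
#' @export
setClass("ResponseCurve",
  slots = c(variable = "character", form = "character", params = "numeric"),
  validity = function(object) {
    need <- switch(object@form,
      gaussian = c("optimum", "breadth"),
      logistic = c("midpoint", "slope"),
      ramp = c("low", "high"),
      return("form must be gaussian, logistic or ramp"))
    if (!all(need %in% names(object@params)))
      return(paste0(object@form, " curve needs params ",
                    paste(need, collapse = ", ")))
    if (object@form == "gaussian" && object@params[["breadth"]] <= 0)
      return("gaussian breadth must be > 0")
    if (object@form == "logistic" && object@params[["slope"]] == 0)
      return("logistic slope must be nonzero")
    if (object@form == "ramp" &&
        object@params[["low"]] == object@params[["high"]])
      return("ramp knots must differ")
    TRUE
  })

#' Construct a ResponseCurve
#'
#' @param variable environmental variable name.
#' @param form "gaussian", "logistic" or "ramp".
#' @param ... form parameters: gaussian takes \code{optimum}, \code{breadth};
#'   logistic takes \code{midpoint}, \code{slope}; ramp takes \code{low},
#'   \code{high}.
#' @return A \linkS4class{ResponseCurve}.
#' @examples
#' responseCurve("SST", "gaussian", optimum = 16, breadth = 3)
#' @export
responseCurve <- function(variable, form, ...) {
  new("ResponseCurve", variable = variable, form = form,
      params = unlist(list(...)))
}

#' ArchetypeSpec: a stylized species' operating-model definition
#'
#' Bundles the habitat-preference curves, the suitability-to-presence
#' conversion, the biomass distribution, the annual population
#' multiplier, and the domain rule of one species archetype.
#'
#' @slot name archetype label (HMS, CPS, GFS for the defaults).
#' @slot curves list of \linkS4class{ResponseCurve}, one per driver.
#' @slot combiner how per-variable suitabilities combine: "product"
#'   (then rescaled by the field maximum), "min" or "geomean".
#' @slot presenceBeta suitability at which presence probability is 0.5.
#' @slot presenceAlpha logistic slope of the conversion; must be < 0 so
#'   that presence probability increases with suitability.
#' @slot biomassMeanlog,biomassSdlog lognormal biomass parameters.
#' @slot multiplierKind "none", "boom-bust" or "recruitment-phase".
#' @slot multiplierParams named list of multiplier parameters.
#' @slot maxDepth domain rule: cells with bathymetry <= maxDepth belong
#'   to the archetype's domain (Inf = full grid).
#' @export
setClass("ArchetypeSpec",
  slots = c(name = "character", curves = "list", combiner = "character",
            presenceBeta = "numeric", presenceAlpha = "numeric",
            biomassMeanlog = "numeric", biomassSdlog = "numeric",
            multiplierKind = "character", multiplierParams = "list",
            maxDepth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@curves, is, TRUE, "ResponseCurve")))
      msg <- c(msg, "curves must be ResponseCurve objects")
    if (object@presenceAlpha >= 0)
      msg <- c(msg, "presenceAlpha must be < 0")
    if (object@biomassSdlog < 0) msg <- c(msg, "biomassSdlog must be >= 0")
    if (!object@combiner %in% c("product", "min", "geomean"))
      msg <- c(msg, "combiner must be product, min or geomean")
    if (!object@multiplierKind %in% c("none", "boom-bust", "recruitment-phase"))
      msg <- c(msg, "unknown multiplier kind")
    if (length(msg)) msg else TRUE
  })

#' Construct an ArchetypeSpec
#'
#' @param name archetype label.
#' @param curves list of \linkS4class{ResponseCurve}.
#' @param combiner "product" (default), "min" or "geomean".
#' @param presenceBeta,presenceAlpha logistic presence-conversion
#'   parameters (alpha < 0; smaller |alpha| gives a sharper threshold).
#' @param biomassMeanlog,biomassSdlog lognormal biomass parameters.
#' @param multiplierKind,multiplierParams annual population-multiplier
#'   kind and parameters.
#' @param maxDepth inshore domain limit in m (Inf = full grid).
#' @return An \linkS4class{ArchetypeSpec}.
#' @export
archetypeSpec <- function(name, curves, combiner = "product",
                          presenceBeta = 0.3, presenceAlpha = -0.05,
                          biomassMeanlog = 2, biomassSdlog = 0.3,
                          multiplierKind = "none",
                          multiplierParams = list(), maxDepth = Inf) {
  new("ArchetypeSpec", name = name, curves = curves, combiner = combiner,
      presenceBeta = presenceBeta, presenceAlpha = presenceAlpha,
      biomassMeanlog = biomassMeanlog, biomassSdlog = biomassSdlog,
      multiplierKind = multiplierKind, multiplierParams = multiplierParams,
      maxDepth = maxDepth)
}

## ---------------------------------------------------------------------------
## Samples
## ---------------------------------------------------------------------------

#' SampleSet: annual random observation draws
#'
#' The observation design of the experiment: a fixed number of random
#' cells per year, carrying both the operating-model truth (presence,
#' biomass) and the environmental covariates of the generating
#' pseudo-ESM.  \code{sdmCovariates} names the covariates visible to the
#' estimation models, which differ from the truth drivers when
#' chlorophyll stands in as the prey-field proxy.
#'
#' @slot data data.frame with columns year, cell, lat, lon, the
#'   environmental variables, bathymetry, presence, biomass.
#' @slot role "train" or "test".
#' @slot archetype archetype name the truth was simulated for.
#' @slot esmId generating pseudo-ESM.
#' @slot sdmCovariates character vector of SDM-facing covariate names.
#' @slot seed integer seed the draw was made with.
#' @export
setClass("SampleSet",
  slots = c(data = "data.frame", role = "character", archetype = "character",
            esmId = "character", sdmCovariates = "character",
            seed = "integer"),
  validity = function(object) {
    need <- c("year", "cell", "lat", "lon", "presence", "biomass")
    if (!all(need %in% names(object@data)))
      return(paste("data must contain", paste(need, collapse = ", ")))
    dup <- duplicated(object@data[, c("year", "cell")])
    if (any(dup)) return("duplicate (year, cell) rows")
    TRUE
  })

## ---------------------------------------------------------------------------
## SDM configuration and fits
## ---------------------------------------------------------------------------

#' SdmConfig: one ensemble member's recipe
#'
#' @slot family "GAM", "GLMM", "BRT" or "MLP".
#' @slot parameterization covariate set: "E" (environmental), "S"
#'   (spatial coordinates), "ES", "ST", "EST", or "Temp" (single
#'   temperature covariate).
#' @slot archetype archetype the member is fitted to.
#' @slot hyper named list of family hyperparameters.
#' @slot seed integer seed for stochastic learners.
#' @export
setClass("SdmConfig",
  slots = c(family = "character", parameterization = "character",
            archetype = "character", hyper = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% c("GAM", "GLMM", "BRT", "MLP"))
      msg <- c(msg, "family must be GAM, GLMM, BRT or MLP")
    if (!object@parameterization %in% c("E", "S", "ES", "ST", "EST", "Temp"))
      msg <- c(msg, "parameterization must be one of E, S, ES, ST, EST, Temp")
    if (length(msg)) msg else TRUE
  })

#' Construct an SdmConfig
#'
#' @param family model family ("GAM", "GLMM", "BRT", "MLP").
#' @param parameterization covariate set ("E", "S", "ES", "ST", "EST",
#'   "Temp").
#' @param archetype archetype name.
#' @param hyper named list of hyperparameter overrides.
#' @param seed integer seed.
#' @return An \linkS4class{SdmConfig}.
#' @examples
#' sdmConfig("BRT", "ES", "CPS")
#' @export
sdmConfig <- function(family, parameterization, archetype = "HMS",
                      hyper = list(), seed = 1L) {
  new("SdmConfig", family = family, parameterization = parameterization,
      archetype = archetype, hyper = hyper, seed = as.integer(seed))
}

#' FittedSdm: a fitted hurdle (delta) model
#'
#' Holds the two submodels of the hurdle: a binary occurrence model and
#' a log-scale positive-biomass model fitted to presence rows only,
#' together with the bookkeeping needed to project: training covariate
#' ranges (for extrapolation accounting), the residual log-variance of
#' the positive part (for the lognormal bias correction), and any
#' family-specific preprocessing (input standardization, spatial basis
#' knots).
#'
#' @slot config the \linkS4class{SdmConfig} that produced the fit.
#' @slot occ,pos fitted submodel objects (family-specific classes).
#' @slot sigma2 residual variance of the log-biomass submodel.
#' @slot trainRanges 2-row matrix (min/max) of training covariates.
#' @slot prep list of preprocessing metadata.
#' @export
setClass("FittedSdm",
  slots = c(config = "SdmConfig", occ = "ANY", pos = "ANY",
            sigma2 = "numeric", trainRanges = "matrix", prep = "list"))

## ---------------------------------------------------------------------------
## Extrapolation reference
## ---------------------------------------------------------------------------

#' ReferenceNiche: the historical multivariate environmental envelope
#'
#' Summary of the reference (fitting-period) environment against which
#' projection-period novelty is scored: per-covariate ranges for the
#' univariate NT1 metric, and the mean, ridge-regularized covariance and
#' maximum reference Mahalanobis distance for the combinatorial NT2
#' metric.
#'
#' @slot covariates covariate names, in order.
#' @slot mins,maxs per-covariate reference range.
#' @slot center reference mean vector.
#' @slot cov reference covariance (ridge-regularized).
#' @slot covInv its inverse.
#' @slot maxD2 maximum squared Mahalanobis distance among reference
#'   points (the NT2 normalizer).
#' @export
setClass("ReferenceNiche",
  slots = c(covariates = "character", mins = "numeric", maxs = "numeric",
            center = "numeric", cov = "matrix", covInv = "matrix",
            maxD2 = "numeric"),
  validity = function(object) {
    if (any(object@mins > object@maxs)) return("min > max for a covariate")
    TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@latMin, "-", object@latMax, "N x",
      object@lonMin, "-", object@lonMax, "E @", object@resolution,
      "deg;", length(object@years), "years (",
      min(object@years), "-", max(object@years), ")\n")
})

setMethod("show", "EsmStyle", function(object) {
  cat("EsmStyle", object@esmId, "\n  trends/decade:",
      paste(names(object@trendPerDecade), round(object@trendPerDecade, 3),
            sep = "=", collapse = " "), "\n")
})

setMethod("show", "EnvField", function(object) {
  cat("EnvField [", esmId(object), "]:", nrow(object), "cells x",
      ncol(object), "years;", length(assayNames(object)), "variables (",
      paste(assayNames(object), collapse = ", "), ")\n")
})

setMethod("show", "TruthField", function(object) {
  b <- assay(object, "biomass")
  cat("TruthField [", metadata(object)$archetype, "x",
      metadata(object)$esmId, "]:", nrow(object), "cells x", ncol(object),
      "years; mean occupancy",
      round(mean(assay(object, "presence")[metadata(object)$domainMask, ]), 3),
      "\n")
})

setMethod("show", "ResponseCurve", function(object) {
  cat("ResponseCurve:", object@variable, object@form, "(",
      paste(names(object@params), object@params, sep = "=", collapse = ", "),
      ")\n")
})

setMethod("show", "ArchetypeSpec", function(object) {
  cat("ArchetypeSpec", object@name, "- drivers:",
      paste(vapply(object@curves, function(c) c@variable, ""),
            collapse = ", "),
      "| multiplier:", object@multiplierKind,
      "| domain depth <=", object@maxDepth, "m\n")
})

setMethod("show", "SampleSet", function(object) {
  cat("SampleSet (", object@role, ")", object@archetype, "x", object@esmId,
      ":", nrow(object@data), "rows,",
      length(unique(object@data$year)), "years; SDM covariates:",
      paste(object@sdmCovariates, collapse = ", "), "\n")
})

setMethod("show", "SdmConfig", function(object) {
  cat("SdmConfig", sdmId(object), "for", object@archetype, "\n")
})

setMethod("show", "FittedSdm", function(object) {
  cat("FittedSdm", sdmId(object@config), "(", object@config@archetype,
      "); log-residual variance", round(object@sigma2, 4), "\n")
})

setMethod("show", "ReferenceNiche", function(object) {
  cat("ReferenceNiche over", paste(object@covariates, collapse = ", "),
      "; max reference D^2 =", round(object@maxD2, 3), "\n")
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for gridded fields and configs
#'
#' \code{esmId} returns the pseudo-ESM label of an \linkS4class{EnvField};
#' \code{envYears} the year axis; \code{gridTable} the static cell table
#' (lat, lon, bathymetry); \code{envVariables} the assay names;
#' \code{sdmId} the canonical "FAMILY_PARAM" member label;
#' \code{sampleData} the data.frame inside a \linkS4class{SampleSet};
#' \code{sdmCovariates} its SDM-facing covariate names.
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("esmId", function(x) standardGeneric("esmId"))
#' @rdname accessors
#' @export
setMethod("esmId", "SummarizedExperiment", function(x) metadata(x)$esmId)

#' @rdname accessors
#' @export
setGeneric("envYears", function(x) standardGeneric("envYears"))
#' @rdname accessors
#' @export
setMethod("envYears", "SummarizedExperiment",
          function(x) as.integer(colData(x)$year))

#' @rdname accessors
#' @export
setGeneric("gridTable", function(x) standardGeneric("gridTable"))
#' @rdname accessors
#' @export
setMethod("gridTable", "SummarizedExperiment", function(x) {
  as.data.frame(rowData(x))
})

#' @rdname accessors
#' @export
setGeneric("envVariables", function(x) standardGeneric("envVariables"))
#' @rdname accessors
#' @export
setMethod("envVariables", "SummarizedExperiment", function(x) assayNames(x))

#' @rdname accessors
#' @export
setGeneric("sdmId", function(x) standardGeneric("sdmId"))
#' @rdname accessors
#' @export
setMethod("sdmId", "SdmConfig",
          function(x) paste(x@family, x@parameterization, sep = "_"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setMethod("sampleData", "SampleSet", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("sdmCovariates", function(x) standardGeneric("sdmCovariates"))
#' @rdname accessors
#' @export
setMethod("sdmCovariates", "SampleSet", function(x) x@sdmCovariates)
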