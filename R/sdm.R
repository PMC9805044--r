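## Hurdle (delta) species distribution models: four families x covariate
## parameterizations, fitted to SampleSets and projected onto forcing.
##
## Family realizations (the families are named for what they emulate,
## not for any single reference implementation):
##   GAM  - penalized regression splines per covariate (mgcv), with a
##          2-D thin-plate spatial smooth for S and a year smooth for T;
##   GLMM - linear (degree-2 polynomial) fixed effects plus a low-rank
##          Gaussian radial-basis spatial surface as a random-effect
##          surrogate, and a linear year term for T;
##   BRT  - stochastic gradient-boosted trees (xgboost; depth 3,
##          500 trees, learning rate 0.05, 75% subsampling);
##   MLP  - single-hidden-layer feedforward network (nnet; 16 units,
##          standardized inputs, weight decay 0.01).

#' Temperature covariate of an archetype
#'
#' Surface temperature for the pelagic archetypes (HMS, CPS), bottom
#' temperature for the groundfish archetype -- the single covariate of
#' the "Temp" (temperature-only) parameterization.
#'
#' @param archetype archetype name.
#' @return "SST" or "BT".
#' @export
tempVariable <- function(archetype) {
  if (archetype == "GFS") "BT" else "SST"
}

#' Construct a SampleSet directly
#'
#' Mainly for constructed test designs; [sampleCells()] is the usual
#' entry point.
#'
#' @param data data.frame with year, cell, lat, lon, covariates,
#'   presence, biomass.
#' @param role,archetype,esmId,sdmCovariates,seed slot values.
#' @return A \linkS4class{SampleSet}.
#' @export
sampleSet <- function(data, role = "train", archetype = "HMS",
                      esmId = "toy", sdmCovariates = character(),
                      seed = 1L) {
  new("SampleSet", data = data, role = role, archetype = archetype,
      esmId = esmId, sdmCovariates = sdmCovariates, seed = as.integer(seed))
}

#' Build the feature table of one SDM configuration
#'
#' Deterministic column order: environmental covariates (in the sample's
#' SDM-covariate order), then spatial coordinates (lat, lon), then the
#' year term.  The "Temp" parameterization uses exactly one column, the
#' archetype's temperature covariate.
#'
#' @param samples a \linkS4class{SampleSet} or data.frame.
#' @param config an \linkS4class{SdmConfig}.
#' @param covariates SDM-facing environmental covariate names; taken
#'   from \code{samples} when it is a SampleSet.
#' @return data.frame of model covariates (plus nothing else).
#' @export
buildDesign <- function(samples, config, covariates = NULL) {
  if (is(samples, "SampleSet")) {
    covariates <- covariates %||% sdmCovariates(samples)
    df <- sampleData(samples)
  } else df <- samples
  par <- config@parameterization
  cols <- character()
  if (par %in% c("E", "ES", "EST")) cols <- c(cols, covariates)
  if (par == "Temp") cols <- tempVariable(config@archetype)
  if (par %in% c("S", "ES", "ST", "EST")) cols <- c(cols, "lat", "lon")
  if (par %in% c("ST", "EST")) cols <- c(cols, "year")
  absent <- setdiff(cols, names(df))
  if (length(absent))
    stop("design covariates absent from samples: ",
         paste(absent, collapse = ", "), call. = FALSE)
  df[, cols, drop = FALSE]
}

## ---------------------------------------------------------------------------
## family fitters: each returns list(model = ..., predictFun = f(model, X))
## ---------------------------------------------------------------------------

## k for a 1-D smooth, capped below the number of unique values
smoothK <- function(x, k = 6) max(3L, min(k, length(unique(x)) - 1L))

fitGam <- function(X, y, binary, hyper, seed) {
  dat <- cbind(X, .y = y)
  terms <- character()
  for (v in setdiff(names(X), c("lat", "lon", "year"))) {
    terms <- c(terms, sprintf("s(%s, k = %d)", v,
                              smoothK(X[[v]], hyper$gamK %||% 6)))
  }
  if (all(c("lat", "lon") %in% names(X))) {
    kk <- max(10L, min(hyper$gamSpatialK %||% 30,
                       nrow(unique(X[, c("lat", "lon")])) - 1L))
    terms <- c(terms, sprintf("s(lon, lat, k = %d)", kk))
  }
  if ("year" %in% names(X))
    terms <- c(terms, sprintf("s(year, k = %d)", smoothK(X$year, 6)))
  if (!length(terms)) terms <- "1"
  f <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fam <- if (binary) binomial() else gaussian()
  m <- suppressWarnings(
    mgcv::bam(f, family = fam, data = dat, discrete = TRUE, nthreads = 1))
  list(model = m,
       predictFun = function(model, X)
         as.numeric(predict(model, newdata = X, type = "response",
                            discrete = FALSE)))
}

## low-rank Gaussian RBF spatial basis
rbfBasis <- function(lat, lon, knots, bw) {
  d2 <- outer(lat, knots$lat, "-")^2 + outer(lon, knots$lon, "-")^2
  B <- exp(-0.5 * d2 / bw^2)
  colnames(B) <- paste0("rbf", seq_len(ncol(B)))
  B
}

glmmFeatures <- function(X, prep) {
  out <- list()
  ## environmental covariates enter with linear + quadratic fixed effects
  ## (standard practice for unimodal niche responses in linear SDMs);
  ## the year term stays strictly linear
  for (v in setdiff(names(X), c("lat", "lon"))) {
    x <- X[[v]]
    out[[v]] <- x
    if (v != "year") out[[paste0(v, "_sq")]] <- x^2
  }
  if (all(c("lat", "lon") %in% names(X)))
    out$B <- rbfBasis(X$lat, X$lon, prep$knots, prep$bw)
  do.call(cbind, out)
}

fitGlmm <- function(X, y, binary, hyper, seed, prep = NULL) {
  if (is.null(prep)) {
    prep <- list()
    if (all(c("lat", "lon") %in% names(X))) {
      nk <- hyper$glmmKnots %||% 5
      klat <- quantile(X$lat, probs = seq(0.05, 0.95, length.out = nk))
      klon <- quantile(X$lon, probs = seq(0.05, 0.95, length.out = nk))
      prep$knots <- expand.grid(lat = klat, lon = klon)
      prep$bw <- 1.5 * mean(c(mean(diff(klat)), mean(diff(klon))))
    }
  }
  M <- glmmFeatures(X, prep)
  dat <- data.frame(.y = y, M)
  m <- if (binary)
    suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  else lm(.y ~ ., data = dat)
  list(model = m, prep = prep,
       predictFun = function(model, X, prep) {
         nd <- data.frame(glmmFeatures(X, prep))
         suppressWarnings(as.numeric(predict(model, newdata = nd,
                                             type = "response")))
       })
}

fitBrt <- function(X, y, binary, hyper, seed) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  params <- list(
    objective = if (binary) "binary:logistic" else "reg:squarederror",
    max_depth = hyper$brtDepth %||% 3,
    eta = hyper$brtEta %||% 0.05,
    subsample = hyper$brtSubsample %||% 0.75,
    nthread = 1, seed = seed)
  m <- xgboost::xgb.train(params = params, data = dm,
                          nrounds = hyper$brtRounds %||% 500, verbose = 0)
  list(model = m,
       predictFun = function(model, X)
         predict(model, xgboost::xgb.DMatrix(as.matrix(X))))
}

fitMlp <- function(X, y, binary, hyper, seed) {
  M <- as.matrix(X)
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  scl[scl == 0] <- 1
  Z <- scale(M, center = ctr, scale = scl)
  set.seed(seed)
  m <- if (binary)
    nnet::nnet(Z, y, size = hyper$mlpSize %||% 16,
               decay = hyper$mlpDecay %||% 0.01,
               maxit = hyper$mlpMaxit %||% 300,
               entropy = TRUE, trace = FALSE, MaxNWts = 5000)
  else
    nnet::nnet(Z, y, size = hyper$mlpSize %||% 16,
               decay = hyper$mlpDecay %||% 0.01,
               maxit = hyper$mlpMaxit %||% 300,
               linout = TRUE, trace = FALSE, MaxNWts = 5000)
  list(model = m, center = ctr, scale = scl,
       predictFun = function(model, X, center, scale)
         as.numeric(predict(model, scale(as.matrix(X), center, scale))))
}

## ---------------------------------------------------------------------------

#' Fit a hurdle (delta) SDM to training samples
#'
#' The occurrence submodel (binary response) is fitted to
#' presence/absence on all rows; the positive-biomass submodel to
#' log(biomass) on presence rows only.  Training covariate ranges and
#' the residual log-variance are stored for projection and
#' extrapolation bookkeeping.
#'
#' @param samples a training \linkS4class{SampleSet} (run
#'   [attachProxyCovariates()] first so the models see the chlorophyll
#'   proxy rather than true prey fields).
#' @param config an \linkS4class{SdmConfig}.
#' @param minPositive minimum positive rows required (default 30).
#' @return A \linkS4class{FittedSdm}.
#' @export
fitHurdle <- function(samples, config, minPositive = 30) {
  stopifnot(is(samples, "SampleSet"), is(config, "SdmConfig"))
  validObject(config)
  df <- sampleData(samples)
  X <- buildDesign(samples, config)
  y <- df$presence
  if (all(y == 1) || all(y == 0))
    stop("unfittable design: training data must contain both presences ",
         "and absences", call. = FALSE)
  if (sum(y == 1) < minPositive)
    stop("unfittable design: fewer than ", minPositive, " positive rows",
         call. = FALSE)

  hyper <- config@hyper
  seedOcc <- childSeed(config@seed, "occ", sdmId(config), config@archetype)
  seedPos <- childSeed(config@seed, "pos", sdmId(config), config@archetype)
  fitter <- switch(config@family, GAM = fitGam, GLMM = fitGlmm,
                   BRT = fitBrt, MLP = fitMlp)

  occ <- fitter(X, y, binary = TRUE, hyper = hyper, seed = seedOcc)
  posRows <- which(y == 1)
  Xp <- X[posRows, , drop = FALSE]
  logb <- log(df$biomass[posRows])
  pos <- if (config@family == "GLMM")
    fitGlmm(Xp, logb, binary = FALSE, hyper = hyper, seed = seedPos,
            prep = occ$prep)
  else fitter(Xp, logb, binary = FALSE, hyper = hyper, seed = seedPos)

  ## residual variance of the log-biomass fit (lognormal bias correction)
  mhat <- predictFamily(pos, Xp)
  sigma2 <- mean((logb - mhat)^2)

  rng <- rbind(min = vapply(X, min, 0), max = vapply(X, max, 0))
  new("FittedSdm", config = config, occ = occ, pos = pos, sigma2 = sigma2,
      trainRanges = rng,
      prep = list(columns = names(X), covariates = sdmCovariates(samples)))
}

predictFamily <- function(fit, X) {
  if (!is.null(fit$center))
    fit$predictFun(fit$model, X, fit$center, fit$scale)
  else if (!is.null(fit$prep))
    fit$predictFun(fit$model, X, fit$prep)
  else fit$predictFun(fit$model, X)
}

#' Project a fitted hurdle SDM
#'
#' Combined biomass is p-hat x exp(m-hat + s^2/2), the occurrence
#' probability times the bias-corrected lognormal mean of the positive
#' part, where s^2 is the training residual variance of the log-biomass
#' submodel.  Covariates are never clipped to the training range: the
#' models extrapolate natively, and extrapolation is measured separately
#' by the novelty metrics.
#'
#' @param fitted a \linkS4class{FittedSdm}.
#' @param newdata a \linkS4class{SampleSet}, a data.frame carrying the
#'   model covariates plus year and cell, or an \linkS4class{EnvField}
#'   (projected on every cell and year).
#' @param years optional year subset when \code{newdata} is an EnvField.
#' @return data.frame (year, cell, pOcc, posMean, biomass).
#' @export
projectSdm <- function(fitted, newdata, years = NULL) {
  stopifnot(is(fitted, "FittedSdm"))
  cfg <- fitted@config
  if (is(newdata, "SampleSet")) {
    df <- sampleData(newdata)
  } else if (is(newdata, "EnvField")) {
    df <- envTable(newdata, years)
  } else df <- newdata
  absent <- setdiff(fitted@prep$columns, names(df))
  if (length(absent))
    stop("missing covariate(s) for projection: ",
         paste(absent, collapse = ", "), call. = FALSE)
  X <- df[, fitted@prep$columns, drop = FALSE]
  p <- clamp(predictFamily(fitted@occ, X), 0, 1)
  m <- predictFamily(fitted@pos, X)
  posMean <- exp(m + fitted@sigma2 / 2)
  data.frame(year = df$year, cell = df$cell, pOcc = p, posMean = posMean,
             biomass = p * posMean)
}

## full-grid covariate table of an EnvField (long format)
envTable <- function(env, years = NULL) {
  yrs <- envYears(env)
  if (!is.null(years)) {
    stopIfNot(all(years %in% yrs), "requested years outside forcing range")
    yrs <- as.integer(years)
  }
  g <- gridTable(env)
  j <- match(yrs, envYears(env))
  df <- data.frame(year = rep(yrs, each = nrow(g)),
                   cell = rep(g$cell, length(yrs)),
                   lat = rep(g$lat, length(yrs)),
                   lon = rep(g$lon, length(yrs)),
                   bathymetry = rep(g$bathymetry, length(yrs)))
  for (v in envVariables(env))
    df[[v]] <- as.vector(assay(env, v)[, j, drop = FALSE])
  df
}

## ---------------------------------------------------------------------------
## ensemble enumeration
## ---------------------------------------------------------------------------

#' Default SDM-type roster and exclusions
#'
#' The default roster lists 15 family x parameterization combinations:
#' GAM (E, S, ES, EST), GLMM (E, ES, ST, EST), BRT (E, ES, ST, EST) and
#' MLP (E, ES, EST).  The default exclusions drop the three types with
#' poor projection-period behavior -- the spatial-only GAM, the
#' spatiotemporal GAM whose unconstrained year smooth extrapolates, and
#' the spatiotemporal GLMM -- leaving the retained 12-member ensemble.
#' The roster is configuration, not a fixed constant.
#'
#' @return \code{defaultRoster()}: data.frame (family,
#'   parameterization); \code{defaultExclusions()}: character vector of
#'   "FAMILY_PARAM" ids.
#' @export
defaultRoster <- function() {
  rbind(
    data.frame(family = "GAM", parameterization = c("E", "S", "ES", "EST")),
    data.frame(family = "GLMM", parameterization = c("E", "ES", "ST", "EST")),
    data.frame(family = "BRT", parameterization = c("E", "ES", "ST", "EST")),
    data.frame(family = "MLP", parameterization = c("E", "ES", "EST")))
}

#' @rdname defaultRoster
#' @export
defaultExclusions <- function() c("GAM_S", "GAM_EST", "GLMM_ST")

#' Enumerate the SDM ensemble
#'
#' Full factorial over archetypes x ESMs x roster types, minus
#' exclusions, in stable order.
#'
#' @param archetypes character vector of archetype names.
#' @param esms character vector of ESM ids.
#' @param roster data.frame (family, parameterization).
#' @param exclusions "FAMILY_PARAM" ids to drop.
#' @return data.frame with one row per ensemble member: archetype, esm,
#'   family, parameterization, sdmId, memberId.
#' @examples
#' nrow(enumerateEnsemble(c("HMS", "CPS", "GFS"),
#'                        paste0("esm", 1:3)))  # 12 x 3 x 3 = 108
#' @export
enumerateEnsemble <- function(archetypes, esms, roster = defaultRoster(),
                              exclusions = defaultExclusions()) {
  roster$sdmId <- paste(roster$family, roster$parameterization, sep = "_")
  roster <- roster[!roster$sdmId %in% exclusions, , drop = FALSE]
  out <- expand.grid(sdmId = roster$sdmId, esm = esms,
                     archetype = archetypes, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- merge(out, roster, by = "sdmId", sort = FALSE)
  out <- out[order(out$archetype, out$esm,
                   match(out$sdmId, roster$sdmId)), ]
  out$memberId <- paste(out$archetype, out$esm, out$sdmId, sep = ".")
  rownames(out) <- NULL
  out[, c("archetype", "esm", "family", "parameterization", "sdmId",
          "memberId")]
}
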