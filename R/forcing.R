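## Environmental forcing: synthetic pseudo-ESM generator and text ingest.
##
## The generator emits annual spring-mean fields directly; each variable
## is   base(cell) + trend * (year - startYear) * nearshore(cell)
##               + decadal sinusoid + AR(1) spatially-correlated noise,
## clipped to physical bounds.  Three divergent default styles stand in
## for downscaled GFDL / HAD / IPSL forcing under a high-emissions
## scenario.

ENV_VARS <- c("SST", "BT", "BO", "MLD", "ZOO50", "ZOO200", "CHL")

#' Build the static cell table of a grid
#'
#' Cells are centers of a regular lat/lon grid.  Bathymetry follows a
#' deterministic shelf--slope--abyssal profile: shallow at the eastern
#' (coastal) boundary, strictly deepening westward toward an abyssal
#' plateau near 4 km, so that inshore (shelf/slope) domain masks are
#' definable by a depth threshold.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @return data.frame with columns \code{cell}, \code{lat}, \code{lon},
#'   \code{bathymetry} (m, positive down) and \code{coastDist} (cells
#'   from the coastal boundary).
#' @examples
#' g <- makeGrid(gridSpec(resolution = 1))
#' nrow(g)  # 18 x 18 = 324
#' @export
makeGrid <- function(spec) {
  stopifnot(is(spec, "GridSpec"))
  validObject(spec)
  res <- spec@resolution
  lats <- seq(spec@latMin + res / 2, spec@latMax - res / 2, by = res)
  lons <- seq(spec@lonMin + res / 2, spec@lonMax - res / 2, by = res)
  g <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("lat", "lon")]
  ## distance from the coastal (eastern) boundary, in cell units
  g$coastDist <- (max(lons) - g$lon) / res
  ## logistic shelf-slope profile: ~90 m at the coast, slope break
  ## around 8 cells offshore, abyssal plateau ~4 km
  g$bathymetry <- 20 + 4000 / (1 + exp(-(g$coastDist - 8) / 2))
  g <- g[order(g$lat, g$lon), ]
  g$cell <- seq_len(nrow(g))
  rownames(g) <- NULL
  g[, c("cell", "lat", "lon", "bathymetry", "coastDist")]
}

#' Default pseudo-ESM styles
#'
#' Three divergent synthetic forcing recipes ("pseudo-GFDL",
#' "pseudo-HAD", "pseudo-IPSL").  All warm at the surface and bottom and
#' lose mixed-layer depth, bottom oxygen and zooplankton, but at
#' different rates; pseudo-HAD is the strongly-forced end member.
#' Decadal variability (30-year period, style-specific phase) is applied
#' to MLD and the zooplankton variables.
#'
#' @return Named list of three \linkS4class{EsmStyle} objects.
#' @export
defaultEsmStyles <- function() {
  noise <- c(SST = 0.30, BT = 0.10, BO = 3.0, MLD = 1.5,
             ZOO50 = 0.35, ZOO200 = 0.50, CHL = 0.05)
  list(
    "pseudo-GFDL" = esmStyle("pseudo-GFDL",
      trendPerDecade = c(SST = 0.20, BT = 0.10, MLD = -0.5, BO = -3.0,
                         ZOO50 = -0.15, ZOO200 = -0.25),
      cycleAmp = c(MLD = 3, ZOO50 = 0.8, ZOO200 = 1.2),
      cyclePeriod = 30, cyclePhase = 0, noiseSd = noise),
    "pseudo-HAD" = esmStyle("pseudo-HAD",
      trendPerDecade = c(SST = 0.45, BT = 0.22, MLD = -1.0, BO = -6.0,
                         ZOO50 = -0.35, ZOO200 = -0.50),
      cycleAmp = c(MLD = 3, ZOO50 = 0.8, ZOO200 = 1.2),
      cyclePeriod = 30, cyclePhase = 2, noiseSd = noise),
    "pseudo-IPSL" = esmStyle("pseudo-IPSL",
      trendPerDecade = c(SST = 0.32, BT = 0.16, MLD = -0.8, BO = -4.5,
                         ZOO50 = -0.25, ZOO200 = -0.38),
      cycleAmp = c(MLD = 3, ZOO50 = 0.8, ZOO200 = 1.2),
      cyclePeriod = 30, cyclePhase = 4, noiseSd = noise))
}

## Climatological base state shared by all pseudo-ESMs: smooth functions
## of latitude, depth and distance from the coast.
baseField <- function(variable, grid) {
  lat <- grid$lat; depth <- grid$bathymetry; d <- grid$coastDist
  switch(variable,
    SST = 20 - 0.45 * (lat - 30),
    BT = 2 + 11 * exp(-depth / 900) - 0.05 * (lat - 30),
    BO = 80 + 3 * (lat - 30) + 40 * exp(-depth / 500),
    MLD = 15 + 0.5 * (lat - 30) + 10 * (1 - exp(-depth / 2000)),
    ZOO50 = 1 + 8 * exp(-d / 6) + 0.10 * (lat - 30),
    ZOO200 = 2 + 12 * exp(-d / 10) + 0.15 * (lat - 30),
    CHL = NA_real_,  # derived from ZOO50, see generateForcing
    stop("unknown variable: ", variable))
}

physicalBounds <- function(variable) {
  switch(variable,
    BO = c(0, Inf), CHL = c(0, Inf), ZOO50 = c(0, Inf), ZOO200 = c(0, Inf),
    MLD = c(0.5, Inf), c(-Inf, Inf))
}

## Spatially-smoothed standard-normal field on the (nlat x nlon) grid.
## White noise convolved with a separable Gaussian kernel and rescaled
## to unit variance.
smoothNoise <- function(nlat, nlon, range) {
  w <- matrix(rnorm(nlat * nlon), nlat, nlon)
  if (range > 0) {
    half <- max(1L, ceiling(3 * range))
    k <- exp(-0.5 * ((-half:half) / range)^2)
    k <- k / sum(k)
    pad <- function(m, n) { # reflect-pad rows by n
      rbind(m[n:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - n + 1), , drop = FALSE])
    }
    conv1 <- function(m) { # filter columns of m with kernel k
      mp <- pad(m, half)
      out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
      out[(half + 1):(half + nrow(m)), , drop = FALSE]
    }
    w <- conv1(w)
    w <- t(conv1(t(w)))
    s <- sd(as.vector(w))
    if (s > 0) w <- w / s
  }
  w
}

#' Generate annual spring-mean forcing for one pseudo-ESM
#'
#' @param spec a \linkS4class{GridSpec}.
#' @param style an \linkS4class{EsmStyle}.
#' @param seed integer seed; identical (spec, style, seed) yields
#'   bit-identical output.
#' @return An \linkS4class{EnvField} with assays SST, BT, BO, MLD,
#'   ZOO50, ZOO200, CHL as (cell x year) matrices.
#' @details Chlorophyll is generated as a noisy proportional proxy of
#'   the 50 m-integrated zooplankton field (CHL = 0.35 ZOO50 + noise),
#'   so that the estimation models' prey proxy is informative but
#'   imperfect, as intended by the proxy-covariate design.
#' @examples
#' env <- generateForcing(gridSpec(resolution = 2, years = 1985:1990),
#'                        defaultEsmStyles()[[1]], seed = 1)
#' env
#' @export
generateForcing <- function(spec, style, seed = 1L) {
  stopifnot(is(spec, "GridSpec"), is(style, "EsmStyle"))
  grid <- makeGrid(spec)
  years <- spec@years
  ny <- length(years)
  ncell <- nrow(grid)
  nlat <- length(unique(grid$lat))
  nlon <- length(unique(grid$lon))
  ## nearshore trend amplification, decaying offshore
  nearW <- 1 + (style@nearshoreAmp - 1) * exp(-grid$coastDist / 6)
  t0 <- min(years)

  assays <- list()
  for (v in setdiff(ENV_VARS, "CHL")) {
    base <- baseField(v, grid)
    trend <- (style@trendPerDecade[v] %||% 0)
    if (is.na(trend)) trend <- 0
    amp <- style@cycleAmp[v]
    amp <- if (is.null(amp) || is.na(amp)) 0 else amp
    nsd <- style@noiseSd[v]
    nsd <- if (is.null(nsd) || is.na(nsd)) 0 else nsd

    m <- matrix(0, ncell, ny)
    ## deterministic components
    for (j in seq_len(ny)) {
      yr <- years[j] - t0
      m[, j] <- base + trend / 10 * yr * nearW +
        amp * sin(2 * pi * yr / style@cyclePeriod + style@cyclePhase)
    }
    ## AR(1)-in-time, spatially-correlated noise
    if (nsd > 0) {
      set.seed(childSeed(seed, "forcing", style@esmId, v))
      phi <- style@arPhi
      eps <- matrix(0, ncell, ny)
      innovSd <- sqrt(1 - phi^2)
      prev <- as.vector(t(smoothNoise(nlat, nlon, style@spatialRange)))
      eps[, 1] <- prev
      for (j in seq_len(ny)[-1]) {
        innov <- as.vector(t(smoothNoise(nlat, nlon, style@spatialRange)))
        prev <- phi * prev + innovSd * innov
        eps[, j] <- prev
      }
      m <- m + nsd * eps
    }
    b <- physicalBounds(v)
    assays[[v]] <- clamp(m, b[1], b[2])
  }
  ## chlorophyll: proxy of ZOO50 plus its own small noise
  chl <- 0.35 * assays[["ZOO50"]]
  nsd <- style@noiseSd["CHL"]
  nsd <- if (is.null(nsd) || is.na(nsd)) 0 else nsd
  if (nsd > 0) {
    set.seed(childSeed(seed, "forcing", style@esmId, "CHL"))
    eps <- matrix(0, ncell, ny)
    prev <- as.vector(t(smoothNoise(nlat, nlon, style@spatialRange)))
    eps[, 1] <- prev
    for (j in seq_len(ny)[-1]) {
      innov <- as.vector(t(smoothNoise(nlat, nlon, style@spatialRange)))
      prev <- style@arPhi * prev + sqrt(1 - style@arPhi^2) * innov
      eps[, j] <- prev
    }
    chl <- chl + nsd * eps
  }
  assays[["CHL"]] <- clamp(chl, 0, Inf)
  ## order assays canonically
  assays <- assays[ENV_VARS]

  newEnvField(assays, grid, years, style@esmId)
}

## internal EnvField constructor
newEnvField <- function(assays, grid, years, esmId) {
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(NULL, NULL)
    a
  })
  se <- SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(grid),
    colData = S4Vectors::DataFrame(year = as.integer(years)))
  metadata(se)$esmId <- esmId
  new("EnvField", se)
}

#' Write forcing to a plain-text long-format table
#'
#' One CSV with columns \code{variable, year, lat, lon, value} plus
#' static \code{bathymetry} rows (year = NA).  The companion of
#' [readForcing()]; round-trips an \linkS4class{EnvField} exactly to
#' within text precision.
#'
#' @param env an \linkS4class{EnvField}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeForcing <- function(env, path) {
  g <- gridTable(env)
  years <- envYears(env)
  rows <- lapply(envVariables(env), function(v) {
    a <- assay(env, v)
    data.frame(variable = v,
               year = rep(years, each = nrow(g)),
               lat = rep(g$lat, length(years)),
               lon = rep(g$lon, length(years)),
               value = as.vector(a))
  })
  bat <- data.frame(variable = "bathymetry", year = NA_integer_,
                    lat = g$lat, lon = g$lon, value = g$bathymetry)
  out <- do.call(rbind, c(rows, list(bat)))
  utils::write.csv(format(out, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read forcing from a long-format table
#'
#' Ingests annual or monthly forcing from a CSV with columns
#' \code{variable, year, [month,] lat, lon, value}.  Monthly tables are
#' reduced to annual spring means over March--May.  A static
#' \code{bathymetry} variable (year = NA) is required.
#'
#' @param path CSV path.
#' @param esmId label to attach to the resulting field.
#' @param variables required dynamic variables; an error names any that
#'   are absent.
#' @return An \linkS4class{EnvField} on the file's grid.
#' @export
readForcing <- function(path, esmId = "ingested", variables = ENV_VARS) {
  x <- utils::read.csv(path)
  need <- c("variable", "year", "lat", "lon", "value")
  stopIfNot(all(need %in% names(x)),
            paste("forcing table must have columns",
                  paste(need, collapse = ", ")))
  missing <- setdiff(variables, unique(x$variable))
  if (length(missing))
    stop("forcing file lacks variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"bathymetry" %in% x$variable)
    stop("forcing file lacks variable(s): bathymetry", call. = FALSE)

  if ("month" %in% names(x)) {
    dyn <- x[x$variable != "bathymetry", ]
    if (any(!dyn$month %in% 1:12))
      stop("invalid month values in time axis", call. = FALSE)
    if (anyDuplicated(dyn[, c("variable", "year", "month", "lat", "lon")]))
      stop("non-monotone time axis: duplicated time steps", call. = FALSE)
    spring <- dyn[dyn$month %in% 3:5, ]
    stopIfNot(nrow(spring) > 0, "no spring (March-May) months present")
    agg <- aggregate(value ~ variable + year + lat + lon, spring, mean)
    x <- rbind(agg, x[x$variable == "bathymetry",
                      c("variable", "year", "lat", "lon", "value")])
  }

  bat <- x[x$variable == "bathymetry", ]
  grid <- bat[order(bat$lat, bat$lon), c("lat", "lon", "value")]
  names(grid)[3] <- "bathymetry"
  grid$cell <- seq_len(nrow(grid))
  res <- if (nrow(grid) > 1) min(diff(sort(unique(grid$lon)))) else 1
  grid$coastDist <- (max(grid$lon) - grid$lon) / res
  grid <- grid[, c("cell", "lat", "lon", "bathymetry", "coastDist")]

  dyn <- x[x$variable != "bathymetry", ]
  years <- sort(unique(dyn$year))
  key <- paste(grid$lat, grid$lon)
  assays <- list()
  for (v in intersect(ENV_VARS, unique(dyn$variable))) {
    a <- matrix(NA_real_, nrow(grid), length(years))
    for (j in seq_along(years)) {
      sl <- dyn[dyn$variable == v & dyn$year == years[j], ]
      idx <- match(paste(sl$lat, sl$lon), key)
      stopIfNot(!anyNA(idx) && length(idx) == nrow(grid),
                paste("incomplete grid for", v, "in year", years[j]))
      a[idx, j] <- sl$value
    }
    assays[[v]] <- a
  }
  newEnvField(assays, grid, years, esmId)
}
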