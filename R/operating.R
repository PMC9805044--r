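## Operating models: simulate "true" habitat suitability, presence and
## biomass per cell-year from an EnvField, virtual-species style.

#' Evaluate a response curve
#'
#' Total function into \[0, 1\]: gaussian curves attain 1 at their
#' optimum and are symmetric about it; logistic curves are monotone with
#' value 0.5 at the midpoint; ramps are linear between their two knots
#' and clamped outside (decreasing when low > high).
#'
#' @param curve a \linkS4class{ResponseCurve}.
#' @param x numeric vector/matrix of environmental values.
#' @return Suitability values in \[0, 1\], same shape as \code{x}.
#' @examples
#' evalResponse(responseCurve("SST", "gaussian", optimum = 18, breadth = 2), 20)
#' @export
evalResponse <- function(curve, x) {
  validObject(curve)
  p <- curve@params
  switch(curve@form,
    gaussian = exp(-0.5 * ((x - p[["optimum"]]) / p[["breadth"]])^2),
    logistic = plogis((x - p[["midpoint"]]) / p[["slope"]]),
    ramp = clamp((x - p[["low"]]) / (p[["high"]] - p[["low"]]), 0, 1))
}

#' Combine per-variable suitabilities into total suitability
#'
#' The default combiner is the product of the per-variable suitabilities,
#' rescaled by the field maximum so the best cell-year scores exactly 1
#' (an all-zero field is returned unchanged).  "min" and "geomean"
#' combiners are available as alternatives and are not rescaled.
#'
#' @param suits list of equally-shaped suitability arrays in \[0, 1\].
#' @param combiner "product", "min" or "geomean".
#' @return Total suitability, same shape as the inputs.
#' @export
combineSuitability <- function(suits, combiner = "product") {
  stopIfNot(length(suits) >= 1, "need at least one suitability layer")
  total <- switch(combiner,
    product = Reduce(`*`, suits),
    min = Reduce(pmin, suits),
    geomean = Reduce(`*`, suits)^(1 / length(suits)),
    stop("combiner must be product, min or geomean", call. = FALSE))
  if (combiner == "product") {
    mx <- max(total)
    if (mx > 0) total <- total / mx
  }
  total
}

#' Logistic suitability-to-presence conversion
#'
#' p = 1 / (1 + exp((s - beta) / alpha)) with alpha < 0, so presence
#' probability increases with suitability, crosses 0.5 at beta, and
#' approaches a step function at beta as alpha approaches 0 from below.
#'
#' @param suitability suitability values in \[0, 1\].
#' @param beta suitability at which presence probability is 0.5.
#' @param alpha logistic slope; must be strictly negative.
#' @return Presence probabilities, same shape as \code{suitability}.
#' @examples
#' presenceProbability(0.6, beta = 0.5, alpha = -0.05)  # 1/(1+exp(-2))
#' @export
presenceProbability <- function(suitability, beta, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha >= 0)
    stop("alpha must be a single negative number (alpha = 0 is invalid)",
         call. = FALSE)
  plogis((suitability - beta) / (-alpha))
}

#' Annual population multiplier series
#'
#' Population-level dynamics applied as a spatially-uniform annual
#' biomass multiplier.  Kinds: \code{none} (always 1);
#' \code{recruitment-phase}, a square wave alternating between a low and
#' a high recruitment level every \code{period} years (40-year full
#' cycle by default), with a linear ramp over \code{rampYears} at each
#' transition; \code{boom-bust}, a two-state (high/low) Markov regime
#' with lognormal jitter.
#'
#' @param kind "none", "boom-bust" or "recruitment-phase".
#' @param years integer vector of years.
#' @param params named list: recruitment-phase takes \code{low},
#'   \code{high}, \code{period}, \code{rampYears}; boom-bust takes
#'   \code{pStayHigh}, \code{pStayLow}, \code{high}, \code{low},
#'   \code{jitterSd}.
#' @param seed integer seed (boom-bust only).
#' @return Numeric vector of multipliers, one per year, all > 0.
#' @export
populationMultiplier <- function(kind, years, params = list(), seed = 1L) {
  years <- as.integer(years)
  n <- length(years)
  switch(kind,
    none = rep(1, n),
    "recruitment-phase" = {
      low <- params$low %||% 0.5
      high <- params$high %||% 1.5
      period <- params$period %||% 20
      ramp <- params$rampYears %||% 2
      t <- years - min(years)
      phase <- (t %/% period) %% 2          # 0 = low, 1 = high (starts low)
      lev <- ifelse(phase == 0, low, high)
      prev <- ifelse(phase == 0, high, low) # level of the preceding phase
      within <- t %% period
      firstPhase <- t < period
      w <- pmin(1, (within + 1) / (ramp + 1))
      out <- ifelse(firstPhase, lev, prev + (lev - prev) * w)
      out
    },
    "boom-bust" = {
      pStayHigh <- params$pStayHigh %||% 0.8
      pStayLow <- params$pStayLow %||% 0.8
      high <- params$high %||% 2.0
      low <- params$low %||% 0.25
      jitterSd <- params$jitterSd %||% 0.2
      set.seed(seed)
      state <- numeric(n)
      state[1] <- as.numeric(runif(1) < 0.5)  # 1 = high
      if (n > 1) for (i in 2:n) {
        stay <- if (state[i - 1] == 1) pStayHigh else pStayLow
        state[i] <- if (runif(1) < stay) state[i - 1] else 1 - state[i - 1]
      }
      lev <- ifelse(state == 1, high, low)
      lev * exp(rnorm(n, 0, jitterSd))
    },
    stop("unknown multiplier kind: ", kind, call. = FALSE))
}

#' Default species archetypes
#'
#' Three stylized California Current species: HMS (highly migratory,
#' albacore-like: SST, MLD and 200 m zooplankton drivers over the full
#' domain), CPS (coastal pelagic, anchovy-like: SST, 50 m zooplankton
#' and bathymetry over inshore waters, with boom-bust population
#' dynamics), and GFS (groundfish, sablefish-like: bottom temperature,
#' bottom oxygen and bathymetry over shelf/slope habitats, with 20-year
#' recruitment phases).  Curve parameters are package defaults chosen so
#' historical suitability has strong spatial structure and late-century
#' forcing pushes a substantial fraction of cells beyond the historical
#' niche.
#'
#' @param presenceAlpha logistic conversion slope (shared; < 0).
#' @param biomassSdlog lognormal biomass sdlog (shared).
#' @return Named list of three \linkS4class{ArchetypeSpec} objects.
#' @export
defaultArchetypes <- function(presenceAlpha = -0.05, biomassSdlog = 0.3) {
  list(
    HMS = archetypeSpec("HMS",
      curves = list(
        responseCurve("SST", "gaussian", optimum = 16, breadth = 3),
        responseCurve("MLD", "gaussian", optimum = 24, breadth = 8),
        responseCurve("ZOO200", "logistic", midpoint = 5, slope = 2)),
      presenceBeta = 0.3, presenceAlpha = presenceAlpha,
      biomassMeanlog = 2, biomassSdlog = biomassSdlog,
      multiplierKind = "none", maxDepth = Inf),
    CPS = archetypeSpec("CPS",
      curves = list(
        responseCurve("SST", "gaussian", optimum = 15, breadth = 2.5),
        responseCurve("ZOO50", "logistic", midpoint = 4, slope = 1.5),
        responseCurve("bathymetry", "ramp", low = 1100, high = 150)),
      presenceBeta = 0.3, presenceAlpha = presenceAlpha,
      biomassMeanlog = 2, biomassSdlog = biomassSdlog,
      multiplierKind = "boom-bust",
      multiplierParams = list(pStayHigh = 0.8, pStayLow = 0.8,
                              high = 2.0, low = 0.25, jitterSd = 0.2),
      maxDepth = 1200),
    GFS = archetypeSpec("GFS",
      curves = list(
        responseCurve("BT", "gaussian", optimum = 7, breadth = 2.5),
        responseCurve("BO", "logistic", midpoint = 100, slope = 20),
        responseCurve("bathymetry", "gaussian", optimum = 600,
                      breadth = 350)),
      presenceBeta = 0.3, presenceAlpha = presenceAlpha,
      biomassMeanlog = 2, biomassSdlog = biomassSdlog,
      multiplierKind = "recruitment-phase",
      multiplierParams = list(low = 0.5, high = 1.5, period = 20,
                              rampYears = 2),
      maxDepth = 1200))
}

## driver values as a (cell x year) matrix, broadcasting static
## bathymetry across years
driverMatrix <- function(env, variable, ny) {
  if (variable == "bathymetry")
    matrix(gridTable(env)$bathymetry, nrow(env), ny)
  else {
    if (!variable %in% envVariables(env))
      stop("driver variable absent from forcing: ", variable, call. = FALSE)
    assay(env, variable)
  }
}

#' Simulate the true species state from forcing
#'
#' The two-step virtual-species procedure: per-variable suitabilities
#' from the archetype's habitat-preference curves are combined into a
#' total suitability (product, field-max rescaled), converted to
#' presence by a sharp logistic function, and, where present, biomass is
#' drawn from a lognormal distribution, scaled by the cell's suitability
#' (habitat-informed biomass) and by the archetype's annual population
#' multiplier.  Absent cells carry zero biomass.  Cells outside the
#' archetype's domain (bathymetry deeper than \code{maxDepth}) and cells
#' of zero suitability are strict absences.
#'
#' @param env an \linkS4class{EnvField}.
#' @param spec an \linkS4class{ArchetypeSpec}.
#' @param seed integer seed; the draw is reproducible.
#' @return A \linkS4class{TruthField} on the same grid and years.
#' @export
drawTruth <- function(env, spec, seed = 1L) {
  stopifnot(is(env, "EnvField"), is(spec, "ArchetypeSpec"))
  ny <- ncol(env)
  years <- envYears(env)
  g <- gridTable(env)
  domain <- g$bathymetry <= spec@maxDepth

  suits <- lapply(spec@curves, function(cv)
    evalResponse(cv, driverMatrix(env, cv@variable, ny)))
  ## combine over the domain only, so the field-max rescaling is taken
  ## over cells the species can occupy
  suit <- combineSuitability(suits, spec@combiner)
  suit[!domain, ] <- 0
  if (spec@combiner == "product") {
    mx <- max(suit)
    if (mx > 0) suit <- suit / mx
  }

  p <- presenceProbability(suit, spec@presenceBeta, spec@presenceAlpha)
  p[suit == 0] <- 0  # zero suitability (incl. out-of-domain) is strict absence

  set.seed(childSeed(seed, "truth", spec@name, esmId(env)))
  pres <- matrix(rbinom(length(p), 1, as.vector(p)), nrow(p), ncol(p))
  M <- populationMultiplier(spec@multiplierKind, years, spec@multiplierParams,
                            seed = childSeed(seed, "multiplier", spec@name,
                                             esmId(env)))
  raw <- matrix(rlnorm(length(p), spec@biomassMeanlog, spec@biomassSdlog),
                nrow(p), ncol(p))
  biomass <- pres * raw * suit * rep(M, each = nrow(p))

  se <- SummarizedExperiment(
    assays = list(suitability = suit, presence = pres, biomass = biomass),
    rowData = rowData(env),
    colData = S4Vectors::DataFrame(year = years, multiplier = M))
  metadata(se)$esmId <- esmId(env)
  metadata(se)$archetype <- spec@name
  metadata(se)$spec <- spec
  metadata(se)$domainMask <- domain
  new("TruthField", se)
}
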