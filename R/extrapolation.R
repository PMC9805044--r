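## Environmental novelty relative to the historical reference niche:
## ExDet-style univariate (NT1) and combinatorial (NT2) extrapolation.

#' Archetype covariate sets for novelty accounting
#'
#' The covariates whose joint historical envelope defines each
#' archetype's reference niche: SST and MLD for HMS; SST, chlorophyll
#' and bathymetry for CPS; BT, BO and bathymetry for GFS.  These are the
#' estimation-model covariates, so novelty is measured in the space the
#' SDMs actually see.
#'
#' @param archetype archetype name.
#' @return Character vector of covariate names.
#' @export
noveltyCovariates <- function(archetype) {
  switch(archetype,
    HMS = c("SST", "MLD"),
    CPS = c("SST", "CHL", "bathymetry"),
    GFS = c("BT", "BO", "bathymetry"),
    stop("unknown archetype: ", archetype, call. = FALSE))
}

#' Build the historical reference niche
#'
#' Reference points are all grid cells of the archetype's domain across
#' the reference years (not just the annual training samples).  Stores
#' per-covariate ranges, the reference mean and ridge-regularized
#' covariance (ridge = 1e-8 x trace), and the maximum reference
#' Mahalanobis distance that normalizes NT2.
#'
#' @param env an \linkS4class{EnvField}.
#' @param covariates covariate names (bathymetry allowed).
#' @param years reference years (the fitting period).
#' @param cells optional cell subset (e.g. an inshore domain mask).
#' @return A \linkS4class{ReferenceNiche}.
#' @export
buildReference <- function(env, covariates, years, cells = NULL) {
  stopifnot(is(env, "EnvField"))
  yrs <- envYears(env)
  stopIfNot(all(years %in% yrs), "reference years outside forcing range")
  j <- match(as.integer(years), yrs)
  g <- gridTable(env)
  cells <- cells %||% g$cell
  P <- referenceMatrix(env, covariates, j, cells)
  stopIfNot(nrow(P) >= length(covariates) + 1,
            "need at least p + 1 reference points")

  mins <- apply(P, 2, min); maxs <- apply(P, 2, max)
  mu <- colMeans(P)
  S <- cov(P)
  S <- S + diag(1e-8 * sum(diag(S)), ncol(S))
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("reference covariance singular after regularization", call. = FALSE))
  d2 <- mahalanobis(P, mu, Sinv, inverted = TRUE)
  new("ReferenceNiche", covariates = covariates, mins = mins, maxs = maxs,
      center = mu, cov = S, covInv = Sinv, maxD2 = max(d2))
}

## (points x covariates) matrix over given year indices and cells
referenceMatrix <- function(env, covariates, j, cells) {
  g <- gridTable(env)
  idx <- match(cells, g$cell)
  cols <- lapply(covariates, function(v) {
    if (v == "bathymetry") rep(g$bathymetry[idx], length(j))
    else {
      if (!v %in% envVariables(env))
        stop("covariate absent from forcing: ", v, call. = FALSE)
      as.vector(assay(env, v)[idx, j, drop = FALSE])
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

asPointMatrix <- function(points, covariates) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1,
                                             dimnames = list(NULL, names(points)))
  points <- as.matrix(points)
  absent <- setdiff(covariates, colnames(points))
  if (length(absent))
    stop("points lack reference covariate(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  points[, covariates, drop = FALSE]
}

#' Univariate extrapolation metric NT1
#'
#' NT1 is the sum over covariates of the (negative) fractional distance
#' outside the reference range: for covariate j with reference range
#' \[min_j, max_j\], UD_j = min\{(x_j - min_j) / (max_j - min_j),
#' (max_j - x_j) / (max_j - min_j), 0\}.  NT1 = 0 exactly when every
#' covariate lies inside its reference range, and is more negative the
#' further outside.
#'
#' @param points matrix/data.frame of points (columns named by
#'   covariate), or a single named vector.
#' @param ref a \linkS4class{ReferenceNiche}.
#' @return Numeric vector of NT1 values (<= 0).
#' @export
nt1 <- function(points, ref) {
  P <- asPointMatrix(points, ref@covariates)
  rng <- ref@maxs - ref@mins
  out <- numeric(nrow(P))
  for (k in seq_along(ref@covariates)) {
    if (rng[k] == 0) {
      off <- P[, k] != ref@mins[k]
      if (any(off))
        stop("zero-range reference covariate '", ref@covariates[k],
             "' with points off the reference value", call. = FALSE)
      next
    }
    ud <- pmin((P[, k] - ref@mins[k]) / rng[k],
               (ref@maxs[k] - P[, k]) / rng[k], 0)
    out <- out + ud
  }
  unname(out)
}

#' Combinatorial extrapolation metric NT2
#'
#' For points inside every univariate range (NT1 = 0), NT2 is the
#' squared Mahalanobis distance to the reference mean divided by the
#' largest squared Mahalanobis distance among reference points; values
#' above 1 mark novel covariate combinations beyond the most extreme
#' reference point.  Calling it on a point with NT1 < 0 is a contract
#' violation.
#'
#' @inheritParams nt1
#' @return Numeric vector of NT2 values (>= 0).
#' @export
nt2 <- function(points, ref) {
  P <- asPointMatrix(points, ref@covariates)
  if (any(nt1(P, ref) < 0))
    stop("nt2 called on point(s) with NT1 < 0 (univariate extrapolation)",
         call. = FALSE)
  mahalanobis(P, ref@center, ref@covInv, inverted = TRUE) / ref@maxD2
}

#' Classify points as analog or novel
#'
#' NT1 < 0: univariate extrapolation; NT1 = 0 and NT2 > 1: combinatorial
#' extrapolation; otherwise analog.  With a single covariate NT2 is
#' undefined and classification falls back to NT1 alone.
#'
#' @inheritParams nt1
#' @return data.frame (nt1, nt2, class).
#' @export
classifyNovelty <- function(points, ref) {
  P <- asPointMatrix(points, ref@covariates)
  v1 <- nt1(P, ref)
  v2 <- rep(NA_real_, nrow(P))
  ok <- v1 == 0
  if (length(ref@covariates) >= 2 && any(ok))
    v2[ok] <- nt2(P[ok, , drop = FALSE], ref)
  cls <- ifelse(v1 < 0, "univariate-extrapolation",
                ifelse(!is.na(v2) & v2 > 1, "combinatorial-extrapolation",
                       "analog"))
  data.frame(nt1 = v1, nt2 = v2, class = cls)
}

#' Percent of novel cells per year
#'
#' The share (0--100) of domain cells in each year whose environment
#' falls outside the historical reference niche (NT1 < 0 or NT2 > 1).
#'
#' @param env an \linkS4class{EnvField}.
#' @param ref a \linkS4class{ReferenceNiche}.
#' @param years years to score (default: all).
#' @param cells optional domain cell subset (must match the reference's).
#' @return data.frame (year, percentNovel).
#' @export
percentNovel <- function(env, ref, years = NULL, cells = NULL) {
  yrs <- envYears(env)
  years <- years %||% yrs
  g <- gridTable(env)
  cells <- cells %||% g$cell
  out <- vapply(as.integer(years), function(yr) {
    j <- match(yr, yrs)
    P <- referenceMatrix(env, ref@covariates, j, cells)
    cl <- classifyNovelty(P, ref)
    100 * mean(cl$class != "analog")
  }, 0)
  data.frame(year = as.integer(years), percentNovel = out)
}
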