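## Variance partitioning of ensemble predictions by dominance analysis:
## how much of the spread in projected biomass is attributable to ESM
## forcing, SDM family, and SDM parameterization.

#' Aggregate member predictions by year and region
#'
#' Sums each ensemble member's combined biomass prediction over the test
#' cells of each region, producing the response rows of the dominance
#' analysis: one row per (member, year, region), with the member's
#' factor levels (esm, family, parameterization) alongside.
#'
#' @param pred data.frame of member predictions with columns esm,
#'   family, parameterization, year, cell, biomass.
#' @param regionMap data.frame (cell, region) assigning each test cell
#'   to a region (see [regionalTag()]).
#' @return data.frame (esm, family, parameterization, year, region,
#'   biomass).
#' @export
aggregatePredictions <- function(pred, regionMap) {
  need <- c("esm", "family", "parameterization", "year", "cell", "biomass")
  absent <- setdiff(need, names(pred))
  stopIfNot(length(absent) == 0,
            paste("predictions lack columns:", paste(absent, collapse = ", ")))
  dt <- data.table::as.data.table(pred)
  rm <- data.table::as.data.table(regionMap[, c("cell", "region")])
  dt <- merge(dt, rm, by = "cell", allow.cartesian = FALSE)
  agg <- dt[, list(biomass = sum(biomass)),
            by = c("esm", "family", "parameterization", "year", "region")]
  agg <- as.data.frame(agg)
  ## completeness: every member must cover every year
  key <- paste(agg$esm, agg$family, agg$parameterization, sep = "/")
  tab <- table(key, agg$year)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    gaps <- paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
                  sep = "@")
    stop("missing member-years in predictions: ",
         paste(utils::head(gaps, 5), collapse = "; "),
         if (length(gaps) > 5) " ...", call. = FALSE)
  }
  agg
}

## all k-subsets of a vector (safe for length-1 vectors, where combn
## would misread the vector as seq_len)
kSubsets <- function(x, k) {
  if (k == 0) return(list(integer()))
  lapply(utils::combn(seq_along(x), k, simplify = FALSE),
         function(ii) x[ii])
}

## R^2 of a linear model given a list of dummy blocks (possibly empty)
blockR2 <- function(y, blocks) {
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, length(y))), blocks))
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - rss / tss
}

#' General dominance analysis over factor groups
#'
#' Fits linear models with each factor's dummy block entering or leaving
#' the design as a unit, over all subsets of the other factors, and
#' assigns each factor its general dominance weight: the average (over
#' subset sizes, then over subsets of that size) of the incremental R^2
#' from adding the factor.  Weights sum to the full model's R^2 -- the
#' defining property of general dominance.  Conditional dominance
#' (incremental R^2 by subset size) and the complete-dominance pairwise
#' comparison are also returned; only the general weights feed the
#' uncertainty shares.
#'
#' @param df data.frame of one year-region cross-section.
#' @param response response column name.
#' @param groups character vector of factor column names (the factor
#'   groups); factors with fewer than two levels present contribute
#'   nothing and receive weight 0.
#' @return list with \code{importance} (named general weights),
#'   \code{r2} (full-model R^2), \code{conditional} (groups x subset
#'   size matrix) and \code{complete} (pairwise logical matrix:
#'   \code{[i, j]} TRUE when i completely dominates j).
#' @export
generalDominance <- function(df, response = "biomass", groups) {
  y <- df[[response]]
  stopIfNot(!is.null(y), paste("no response column", response))
  m <- length(groups)
  blocks <- lapply(groups, function(g) {
    f <- factor(df[[g]])
    if (nlevels(f) < 2) return(NULL)
    model.matrix(~f)[, -1, drop = FALSE]
  })
  names(blocks) <- groups
  if (length(unique(y)) < 2) {
    warning("constant response; all dominance weights are 0")
    imp <- setNames(rep(0, m), groups)
    return(list(importance = imp, r2 = 0,
                conditional = matrix(0, m, m, dimnames = list(groups, NULL)),
                complete = matrix(NA, m, m, dimnames = list(groups, groups))))
  }

  ## R^2 of every subset of groups, keyed by sorted member string
  subsets <- lapply(0:(2^m - 1), function(b) which(bitwAnd(b, 2^(0:(m - 1))) > 0))
  r2 <- vapply(subsets, function(s)
    blockR2(y, blocks[s][!vapply(blocks[s], is.null, TRUE)]), 0)
  keyOf <- function(s) paste0("s", paste(sort(s), collapse = ","))
  names(r2) <- vapply(subsets, keyOf, "")

  conditional <- matrix(NA_real_, m, m, dimnames = list(groups, NULL))
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    incByK <- numeric(m)
    for (k in 0:(m - 1)) {
      subs <- kSubsets(others, k)
      inc <- vapply(subs, function(s)
        r2[[keyOf(c(s, i))]] - r2[[keyOf(s)]], 0)
      incByK[k + 1] <- mean(inc)
    }
    conditional[i, ] <- incByK
  }
  importance <- setNames(rowMeans(conditional), groups)

  ## complete dominance: i dominates j if i's increment >= j's over every
  ## subset of the remaining groups
  complete <- matrix(NA, m, m, dimnames = list(groups, groups))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    rest <- setdiff(seq_len(m), c(i, j))
    subs <- unlist(lapply(0:length(rest), function(k) kSubsets(rest, k)),
                   recursive = FALSE)
    di <- vapply(subs, function(s) r2[[keyOf(c(s, i))]] - r2[[keyOf(s)]], 0)
    dj <- vapply(subs, function(s) r2[[keyOf(c(s, j))]] - r2[[keyOf(s)]], 0)
    complete[i, j] <- all(di >= dj)
  }

  list(importance = importance, r2 = r2[[keyOf(seq_len(m))]],
       conditional = conditional, complete = complete)
}

#' Normalize dominance weights into uncertainty shares
#'
#' Shares are the general dominance weights divided by their sum, so the
#' three sources (ESM, SDM type, SDM parameterization) partition the
#' explained variance; residual variance is excluded.  Tiny negative
#' weights from numerical noise (>= -1e-10) are clipped to zero.  An
#' all-zero weight vector yields NA shares (undefined year).
#'
#' @param importance named numeric vector of dominance weights.
#' @return Named numeric shares summing to 1 (or NAs).
#' @export
relativeShares <- function(importance) {
  if (any(importance < -1e-10))
    stop("negative dominance weights beyond numerical noise", call. = FALSE)
  imp <- pmax(importance, 0)
  tot <- sum(imp)
  if (tot == 0) return(setNames(rep(NA_real_, length(imp)), names(imp)))
  imp / tot
}

#' Dominance-based uncertainty shares per year and region
#'
#' Runs the dominance analysis on each (year, region) cross-section of
#' aggregated member predictions and returns the relative shares of ESM,
#' SDM family (type), and SDM parameterization, with the full-model R^2.
#'
#' @param agg output of [aggregatePredictions()].
#' @return data.frame (year, region, shareEsm, shareType, shareParam,
#'   r2).
#' @export
dominanceShares <- function(agg) {
  groups <- c("esm", "family", "parameterization")
  combos <- unique(agg[, c("year", "region")])
  combos <- combos[order(combos$region, combos$year), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- agg[agg$year == combos$year[i] & agg$region == combos$region[i], ]
    d <- generalDominance(s, response = "biomass", groups = groups)
    sh <- relativeShares(d$importance)
    data.frame(year = combos$year[i], region = combos$region[i],
               shareEsm = sh[["esm"]], shareType = sh[["family"]],
               shareParam = sh[["parameterization"]], r2 = d$r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
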