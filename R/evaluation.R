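## Projection scoring: annual Spearman rank correlation, occurrence AUC,
## 11-year running means, regional tags, and ensemble spread.

#' Annual Spearman correlation between truth and prediction
#'
#' Rank correlation (average ranks for ties -- the many true zeros tie
#' heavily) between observed and predicted biomass, pooled over the test
#' cells within each year.  Years where either side is constant have no
#' defined rank correlation and are recorded as NA.
#'
#' @param truth,pred data.frames with columns year, cell and the value
#'   column (\code{biomass} by default).
#' @param value value column name.
#' @return data.frame (year, rho, n).
#' @export
spearmanByYear <- function(truth, pred, value = "biomass") {
  m <- merge(truth[, c("year", "cell", value)],
             pred[, c("year", "cell", value)],
             by = c("year", "cell"), suffixes = c(".obs", ".hat"))
  yrs <- sort(unique(m$year))
  rho <- vapply(yrs, function(yr) {
    s <- m[m$year == yr, ]
    a <- s[[paste0(value, ".obs")]]; b <- s[[paste0(value, ".hat")]]
    if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
    cor(a, b, method = "spearman")
  }, 0)
  n <- vapply(yrs, function(yr) sum(m$year == yr), 0L)
  data.frame(year = yrs, rho = rho, n = n)
}

#' Annual occurrence AUC
#'
#' Area under the ROC curve of the occurrence probabilities against true
#' presence, by the Mann-Whitney formulation (tied scores earn half
#' credit), per year.  Years with a single class are NA.
#'
#' @param truth data.frame with year, cell, presence.
#' @param pred data.frame with year, cell, pOcc.
#' @return data.frame (year, auc, n).
#' @export
aucByYear <- function(truth, pred) {
  m <- merge(truth[, c("year", "cell", "presence")],
             pred[, c("year", "cell", "pOcc")], by = c("year", "cell"))
  yrs <- sort(unique(m$year))
  auc <- vapply(yrs, function(yr) {
    s <- m[m$year == yr, ]
    aucMW(s$presence, s$pOcc)
  }, 0)
  n <- vapply(yrs, function(yr) sum(m$year == yr), 0L)
  data.frame(year = yrs, auc = auc, n = n)
}

## Mann-Whitney AUC with half-credit ties
aucMW <- function(presence, score) {
  n1 <- sum(presence == 1); n0 <- sum(presence == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)  # average ranks
  (sum(r[presence == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Centered running mean
#'
#' Centered moving average with an odd window; partial windows at the
#' series edges use the available points, so constant series are
#' unchanged and linear series are unchanged at interior points.
#'
#' @param x numeric series (NA allowed; ignored within windows).
#' @param window odd window length (11 by default, the smoothing used
#'   for all reported time series).
#' @return Smoothed series, same length.
#' @export
runningMean <- function(x, window = 11) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Latitudinal region of a cell
#'
#' North above 40 degrees N, central from 34.5 to 40 (both boundaries
#' assigned to central), south below 34.5.
#'
#' @param lat latitude(s) in degrees N.
#' @return Character vector in \{"north", "central", "south"\}.
#' @export
regionalTag <- function(lat) {
  ifelse(lat > 40, "north", ifelse(lat >= 34.5, "central", "south"))
}

#' Ensemble spread of a per-member annual statistic
#'
#' Elementwise min / mean / max / range across ensemble members sharing
#' a year, e.g. of annual correlation or predicted biomass.
#'
#' @param df data.frame with columns year, member, value.
#' @param value value column name.
#' @return data.frame (year, min, mean, max, range, nMembers).
#' @export
ensembleSpread <- function(df, value = "value") {
  stopIfNot(length(unique(df$member)) >= 2,
            "ensemble spread needs at least 2 members")
  yrs <- sort(unique(df$year))
  out <- lapply(yrs, function(yr) {
    v <- df[[value]][df$year == yr]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(year = yr, min = NA_real_, mean = NA_real_,
                        max = NA_real_, range = NA_real_, nMembers = 0L))
    data.frame(year = yr, min = min(v), mean = mean(v), max = max(v),
               range = max(v) - min(v),
               nMembers = length(v))
  })
  do.call(rbind, out)
}
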