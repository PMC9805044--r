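## Shared fixtures, built in code at test time.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

## small deterministic forcing field: no noise, no cycle, optional trend
flatStyle <- function(esmId = "flat", trends = numeric(), nearshoreAmp = 1) {
  esmStyle(esmId, trendPerDecade = trends, cycleAmp = numeric(),
           noiseSd = numeric(), nearshoreAmp = nearshoreAmp)
}

tinyGrid <- function(years = 1985:1990, resolution = 2) {
  gridSpec(resolution = resolution, years = years)
}

## Noiseless monotone hurdle toy: biomass = 2 * SST on presences, sharp
## occurrence threshold near the low end of the SST range.  The absence
## fraction is kept small (~13%) because heavy zero ties impose a
## mechanical ceiling on the pooled Spearman correlation (a perfect
## model scores ~sqrt(1 - q^3) when a fraction q of truth rows tie).
monotoneToy <- function(n = 800, seed = 42) {
  set.seed(seed)
  sst <- runif(n, 8, 22)
  pres <- as.integer(sst > 9.8)
  df <- data.frame(year = rep(1985:1988, length.out = n),
                   cell = seq_len(n),
                   lat = runif(n, 30, 48), lon = runif(n, -134, -116),
                   SST = sst, presence = pres,
                   biomass = pres * 2 * sst)
  sampleSet(df, role = "train", archetype = "HMS", esmId = "toy",
            sdmCovariates = "SST")
}

## independent brute-force ExDet classifier (loops, no shared code path)
bruteNovelty <- function(P, refP) {
  mins <- apply(refP, 2, min); maxs <- apply(refP, 2, max)
  mu <- colMeans(refP)
  S <- cov(refP); S <- S + diag(1e-8 * sum(diag(S)), ncol(S))
  Si <- solve(S)
  dref <- apply(refP, 1, function(r) t(r - mu) %*% Si %*% (r - mu))
  maxD2 <- max(dref)
  out <- character(nrow(P))
  for (i in seq_len(nrow(P))) {
    x <- P[i, ]
    ud <- 0
    for (j in seq_along(x)) {
      rng <- maxs[j] - mins[j]
      ud <- ud + min((x[j] - mins[j]) / rng, (maxs[j] - x[j]) / rng, 0)
    }
    if (ud < 0) out[i] <- "univariate-extrapolation"
    else {
      d2 <- as.numeric(t(x - mu) %*% Si %*% (x - mu))
      out[i] <- if (d2 / maxD2 > 1) "combinatorial-extrapolation" else "analog"
    }
  }
  out
}

## independent all-subsets dominance oracle built on lm()
bruteDominance <- function(df, response, groups) {
  m <- length(groups)
  r2of <- function(gs) {
    if (!length(gs)) return(0)
    f <- as.formula(paste(response, "~", paste(gs, collapse = "+")))
    summary(lm(f, data = df))$r.squared
  }
  imp <- setNames(numeric(m), groups)
  for (g in groups) {
    others <- setdiff(groups, g)
    byK <- numeric(m)
    for (k in 0:(m - 1)) {
      subs <- if (k == 0) list(character()) else {
        idx <- utils::combn(seq_along(others), k, simplify = FALSE)
        lapply(idx, function(ii) others[ii])
      }
      byK[k + 1] <- mean(vapply(subs, function(s)
        r2of(c(s, g)) - r2of(s), 0))
    }
    imp[g] <- mean(byK)
  }
  list(importance = imp, r2 = r2of(groups))
}

## the default synthetic experiment, run once and shared across test
## files (the expensive acceptance fixture)
.experimentCache <- new.env(parent = emptyenv())
defaultExperiment <- function() {
  if (is.null(.experimentCache$res)) {
    cfg <- experimentConfig(masterSeed = 1)
    .experimentCache$res <- suppressWarnings(
      runExperiment(cfg, verbose = FALSE))
  }
  .experimentCache$res
}
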