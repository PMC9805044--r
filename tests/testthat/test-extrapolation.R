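## direct construction of a reference niche from a points matrix
nicheOf <- function(P) {
  S <- cov(P); S <- S + diag(1e-8 * sum(diag(S)), ncol(S))
  Si <- solve(S)
  new("ReferenceNiche", covariates = colnames(P),
      mins = apply(P, 2, min), maxs = apply(P, 2, max),
      center = colMeans(P), cov = S, covInv = Si,
      maxD2 = max(mahalanobis(P, colMeans(P), Si, inverted = TRUE)))
}

test_that("NT1 is the summed fractional range exceedance", {
  P <- cbind(a = c(0, 10), b = c(0, 20))
  ref <- nicheOf(P)
  expect_equal(nt1(cbind(a = 5, b = 10), ref), 0)
  expect_equal(nt1(cbind(a = c(0, 10), b = c(0, 20)), ref), c(0, 0))
  ## one covariate 10% of its range below min
  expect_equal(nt1(cbind(a = -1, b = 10), ref), -0.1)
  ## two covariates each 20% beyond their ranges: UD terms add
  expect_equal(nt1(cbind(a = 12, b = -4), ref), -0.4)
  ## zero-range covariate: equal passes, off-value errors
  P2 <- cbind(a = c(0, 10), b = c(3, 3))
  ref2 <- new("ReferenceNiche", covariates = c("a", "b"),
              mins = c(a = 0, b = 3), maxs = c(a = 10, b = 3),
              center = c(5, 3), cov = diag(2), covInv = diag(2), maxD2 = 1)
  expect_equal(nt1(cbind(a = 5, b = 3), ref2), 0)
  expect_error(nt1(cbind(a = 5, b = 4), ref2), "zero-range")
})

test_that("NT2 is the Mahalanobis ratio, anchored at the extreme reference point", {
  ## toy with identity covariance, mean (0,0), max reference D^2 = 2
  ref <- new("ReferenceNiche", covariates = c("a", "b"),
             mins = c(a = -2, b = -2), maxs = c(a = 2, b = 2),
             center = c(0, 0), cov = diag(2), covInv = diag(2), maxD2 = 2)
  expect_equal(nt2(cbind(a = 0, b = 0), ref), 0)
  expect_equal(nt2(cbind(a = 1, b = 1), ref), 1)  # D^2 = 2, ratio 2/2
  expect_equal(nt2(cbind(a = 2, b = 0), ref), 2)
  ## contract: NT2 is only defined for univariate-analog points
  expect_error(nt2(cbind(a = 5, b = 0), ref), "NT1")

  ## reference point attaining the max D^2 scores exactly 1; brute-force
  ## scan over reference points reproduces the stored normalizer
  set.seed(2)
  P <- cbind(a = rnorm(40), b = rnorm(40))
  refP <- nicheOf(P)
  d2 <- apply(P, 1, function(r)
    t(r - refP@center) %*% refP@covInv %*% (r - refP@center))
  expect_equal(max(d2), refP@maxD2, tolerance = 1e-10)
  iMax <- which.max(d2)
  expect_equal(nt2(P[iMax, , drop = FALSE], refP), 1, tolerance = 1e-10)

  ## two-point degenerate reference survives regularization
  P3 <- cbind(a = c(0, 1), b = c(0, 1))
  ref3 <- nicheOf(P3)
  d3 <- apply(P3, 1, function(r)
    t(r - ref3@center) %*% ref3@covInv %*% (r - ref3@center))
  expect_equal(max(d3), ref3@maxD2)
})

test_that("classification agrees with an independent brute-force implementation", {
  set.seed(7)
  for (rep in 1:3) {
    refP <- cbind(x = rnorm(100, 10, 2), y = rnorm(100, 5, 1),
                  z = runif(100, 0, 4))
    refP[, "y"] <- refP[, "y"] + 0.5 * refP[, "x"]  # correlated covariates
    ref <- nicheOf(refP)
    pts <- cbind(x = rnorm(100, 10, 4), y = rnorm(100, 10, 3),
                 z = runif(100, -1, 5))
    got <- classifyNovelty(pts, ref)$class
    want <- bruteNovelty(pts, refP)
    expect_identical(got, want)
    expect_true(any(got != "analog"))  # instance actually exercises novelty
  }
})

test_that("NT1 and NT2 are invariant to affine covariate rescaling", {
  set.seed(12)
  refP <- cbind(x = rnorm(60, 4, 1), y = rnorm(60, 8, 3))
  pts <- cbind(x = rnorm(20, 4, 2), y = rnorm(20, 8, 5))
  ref <- nicheOf(refP)
  cl1 <- classifyNovelty(pts, ref)
  ## x -> 100 x - 7 applied to reference and points alike
  refP2 <- refP; refP2[, "x"] <- 100 * refP2[, "x"] - 7
  pts2 <- pts; pts2[, "x"] <- 100 * pts2[, "x"] - 7
  cl2 <- classifyNovelty(pts2, nicheOf(refP2))
  expect_equal(cl1$nt1, cl2$nt1, tolerance = 1e-8)
  expect_equal(cl1$nt2, cl2$nt2, tolerance = 1e-4)
  expect_identical(cl1$class, cl2$class)
})

test_that("reference niches from forcing self-classify as analog", {
  env <- generateForcing(tinyGrid(years = 1985:2000, resolution = 2),
                         defaultEsmStyles()[[1]], seed = 41)
  ref <- buildReference(env, c("SST", "MLD"), years = 1985:2000)
  pn <- percentNovel(env, ref, years = 1985:2000)
  expect_equal(pn$percentNovel, rep(0, 16))
  ## single-covariate fallback classifies by NT1 alone
  ref1 <- buildReference(env, "SST", years = 1985:2000)
  cl <- classifyNovelty(cbind(SST = c(15, 1e3)), ref1)
  expect_identical(cl$class,
                   c("analog", "univariate-extrapolation"))
  expect_true(all(is.na(cl$nt2)))
})

test_that("percent-novel counts hand-classified cells and grows under pure trend", {
  set.seed(3)
  refP <- cbind(x = runif(50), y = runif(50))
  ref <- nicheOf(refP)
  pts <- rbind(refP[1:7, ], cbind(x = c(2, 3, -1), y = c(0.5, 0.2, 0.9)))
  cl <- classifyNovelty(pts, ref)
  expect_equal(100 * mean(cl$class != "analog"), 30)

  ## pure warming trend, no noise: novelty is monotone non-decreasing
  spec <- gridSpec(resolution = 2, years = 1985:2100)
  env <- generateForcing(spec, flatStyle(trends = c(SST = 0.4, MLD = -0.8)),
                         seed = 1)
  ref2 <- buildReference(env, c("SST", "MLD"), years = 1985:2010)
  pn <- percentNovel(env, ref2)
  expect_true(all(diff(pn$percentNovel) >= -1e-9))
  expect_equal(pn$percentNovel[pn$year <= 2010], rep(0, 26))
  expect_gt(pn$percentNovel[pn$year == 2100], 25)
})
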