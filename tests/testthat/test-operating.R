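test_that("response curves match their closed forms", {
  gc <- responseCurve("SST", "gaussian", optimum = 18, breadth = 2)
  expect_equal(evalResponse(gc, 18), 1.0)
  expect_equal(evalResponse(gc, 20), exp(-0.5))
  expect_equal(evalResponse(gc, 16), evalResponse(gc, 20))  # symmetry
  lc <- responseCurve("ZOO", "logistic", midpoint = 4, slope = 1.5)
  expect_equal(evalResponse(lc, 4), 0.5)
  expect_true(all(diff(evalResponse(lc, seq(0, 10, 0.1))) > 0))
  rc <- responseCurve("bathymetry", "ramp", low = 1100, high = 150)
  expect_equal(evalResponse(rc, 100), 1)
  expect_equal(evalResponse(rc, 1500), 0)
  expect_equal(evalResponse(rc, 625), 0.5)
  ## curves are total functions into [0, 1]
  for (cv in list(gc, lc, rc)) {
    v <- evalResponse(cv, seq(-1e4, 1e4, length.out = 501))
    expect_true(all(v >= 0 & v <= 1))
  }
  ## monotone approach to the gaussian optimum never decreases suitability
  x <- seq(5, 18, 0.5)
  expect_true(all(diff(evalResponse(gc, x)) > 0))
})

test_that("suitability combination is a rescaled product with annihilating zeros", {
  expect_equal(combineSuitability(list(1, 1, 1)), 1)
  expect_equal(combineSuitability(list(0.7, 0, 0.9)), 0)
  ## 2-cell toy: products (0.4, 0.2), field max 0.4 -> (1, 0.5)
  s1 <- c(0.5, 0.4); s2 <- c(0.8, 0.5)
  expect_equal(combineSuitability(list(s1, s2)), c(1, 0.5))
  ## all-zero field: rescaling skipped
  expect_equal(combineSuitability(list(c(0, 0), c(0, 0))), c(0, 0))
  ## alternatives
  expect_equal(combineSuitability(list(c(0.2, 0.6), c(0.4, 0.3)), "min"),
               c(0.2, 0.3))
})

test_that("presence conversion is logistic in suitability with alpha < 0", {
  expect_equal(presenceProbability(0.3, beta = 0.3, alpha = -0.1), 0.5)
  expect_equal(presenceProbability(0.6, beta = 0.5, alpha = -0.05),
               1 / (1 + exp(-2)))
  s <- seq(0, 1, 0.01)
  expect_true(all(diff(presenceProbability(s, 0.5, -0.05)) > 0))
  ## alpha -> 0- approaches a step at beta
  p <- presenceProbability(c(0.49, 0.51), 0.5, -1e-6)
  expect_equal(p, c(0, 1), tolerance = 1e-12)
  expect_error(presenceProbability(0.5, 0.5, 0), "alpha")
  expect_error(presenceProbability(0.5, 0.5, 0.1), "alpha")
})

test_that("population multipliers: identity, phased recruitment, boom-bust occupancy", {
  expect_equal(populationMultiplier("none", 1985:2000), rep(1, 16))
  expect_error(populationMultiplier("cyclic", 1985), "unknown")

  ## 20-year phases starting low; pure square wave has autocorrelation
  ## peaking at the full 40-year cycle
  yrs <- 1985:2224
  m <- populationMultiplier("recruitment-phase", yrs,
                            list(low = 0.5, high = 1.5, period = 20,
                                 rampYears = 0))
  expect_equal(unique(m[1:20]), 0.5)
  expect_equal(unique(m[21:40]), 1.5)
  ac <- acf(m, lag.max = 60, plot = FALSE)$acf[-1]
  ## short lags are high because the wave is piecewise constant; among
  ## lags past the half-period trough the peak sits at the 40-yr cycle
  expect_equal(which.max(ac[10:60]) + 9L, 40L)
  expect_lt(ac[20], 0)  # half-period anticorrelation
  ## ramped transitions stay within the two levels
  ms <- populationMultiplier("recruitment-phase", yrs,
                             list(low = 0.5, high = 1.5, period = 20,
                                  rampYears = 2))
  expect_true(all(ms >= 0.5 & ms <= 1.5))
  expect_equal(ms[22], 0.5 + (1.5 - 0.5) * 2 / 3)  # mid-ramp point

  ## boom-bust long-run high-state occupancy matches the Markov
  ## stationary distribution: pi_high = (1-pLow)/((1-pHigh)+(1-pLow))
  mb <- populationMultiplier("boom-bust", seq_len(10000) + 1984,
                             list(pStayHigh = 0.8, pStayLow = 0.6,
                                  high = 2, low = 0.25, jitterSd = 0),
                             seed = 99)
  piHigh <- 0.4 / (0.2 + 0.4)
  expect_lt(abs(mean(mb == 2) - piHigh), 0.03)
  ## reproducible under seed
  mb2 <- populationMultiplier("boom-bust", seq_len(100) + 1984,
                              list(), seed = 7)
  mb3 <- populationMultiplier("boom-bust", seq_len(100) + 1984,
                              list(), seed = 7)
  expect_identical(mb2, mb3)
  expect_true(all(mb2 > 0))
})

test_that("simulated truth respects the hurdle, domain mask and degenerate limits", {
  env <- generateForcing(tinyGrid(years = 1985:1994, resolution = 1),
                         defaultEsmStyles()[[1]], seed = 21)
  arch <- defaultArchetypes()
  tr <- drawTruth(env, arch$CPS, seed = 21)
  p <- assay(tr, "presence"); b <- assay(tr, "biomass")
  s <- assay(tr, "suitability")
  expect_true(all((b > 0) == (p == 1)))        # hurdle consistency
  expect_true(all(s >= 0 & s <= 1))
  ## inshore mask: identically zero outside
  outside <- !metadata(tr)$domainMask
  expect_true(any(outside))
  expect_true(all(b[outside, ] == 0) && all(p[outside, ] == 0))
  expect_true(all(p[s == 0] == 0))             # zero suitability -> absence
  ## reproducibility
  tr2 <- drawTruth(env, arch$CPS, seed = 21)
  expect_identical(assay(tr2, "biomass"), b)
  ## missing driver errors by name
  badSpec <- archetypeSpec("X", list(responseCurve("O2", "gaussian",
                                                   optimum = 1, breadth = 1)))
  expect_error(drawTruth(env, badSpec, 1), "O2")

  ## degenerate lognormal (sdlog = 0, multiplier none): biomass equals
  ## exp(meanlog) x suitability exactly on present cells
  det <- archetypeSpec("DET",
    curves = list(responseCurve("SST", "gaussian", optimum = 16, breadth = 4)),
    presenceBeta = 0.2, presenceAlpha = -0.05,
    biomassMeanlog = 1.5, biomassSdlog = 0)
  td <- drawTruth(env, det, seed = 3)
  bp <- assay(td, "biomass"); sp <- assay(td, "suitability")
  pp <- assay(td, "presence")
  expect_equal(bp[pp == 1], exp(1.5) * sp[pp == 1], tolerance = 1e-12)
})

test_that("mean positive biomass matches the lognormal closed form", {
  ## flat forcing, near-saturating suitability and presence: ~1e5 draws
  spec <- gridSpec(resolution = 1, years = 1985:2294)
  env <- generateForcing(spec, flatStyle(), seed = 1)
  wide <- archetypeSpec("WIDE",
    curves = list(responseCurve("SST", "logistic", midpoint = -100, slope = 1)),
    presenceBeta = 0.2, presenceAlpha = -0.01,
    biomassMeanlog = 2, biomassSdlog = 0.3)
  tr <- drawTruth(env, wide, seed = 5)
  b <- assay(tr, "biomass"); p <- assay(tr, "presence")
  s <- assay(tr, "suitability")
  expect_gt(sum(p == 1), 1e5)
  ## suitability is 1 everywhere (constant field rescaled by its max)
  expect_equal(unique(as.vector(s)), 1)
  mc <- mean(b[p == 1])
  expect_lt(abs(mc / (exp(2 + 0.3^2 / 2)) - 1), 0.01)
})

test_that("warming forcing shifts pelagic biomass northward", {
  spec <- gridSpec(resolution = 1, years = 1985:2100)
  env <- generateForcing(spec, defaultEsmStyles()[["pseudo-HAD"]], seed = 13)
  arch <- defaultArchetypes()
  yrs <- envYears(env)
  lat <- gridTable(env)$lat
  for (a in c("HMS", "CPS")) {
    tr <- drawTruth(env, arch[[a]], seed = 13)
    b <- assay(tr, "biomass")
    wlat <- function(cols) {
      tot <- rowSums(b[, cols, drop = FALSE])
      sum(lat * tot) / sum(tot)
    }
    expect_gt(wlat(which(yrs >= 2075)), wlat(which(yrs <= 2010)))
  }
})
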