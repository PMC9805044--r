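test_that("design matrices have the configured columns in deterministic order", {
  df <- data.frame(year = 1, cell = 1, lat = 40, lon = -125,
                   SST = 15, CHL = 2, bathymetry = 300, BT = 6, BO = 100,
                   presence = 1, biomass = 3)
  ss <- sampleSet(df, archetype = "CPS",
                  sdmCovariates = c("SST", "CHL", "bathymetry"))
  expect_equal(names(buildDesign(ss, sdmConfig("BRT", "ES", "CPS"))),
               c("SST", "CHL", "bathymetry", "lat", "lon"))
  expect_equal(names(buildDesign(ss, sdmConfig("GAM", "Temp", "GFS"))), "BT")
  expect_equal(names(buildDesign(ss, sdmConfig("GAM", "Temp", "CPS"))), "SST")
  expect_equal(names(buildDesign(ss, sdmConfig("GLMM", "S", "CPS"))),
               c("lat", "lon"))
  expect_equal(names(buildDesign(ss, sdmConfig("MLP", "EST", "CPS"))),
               c("SST", "CHL", "bathymetry", "lat", "lon", "year"))
  ## determinism
  expect_identical(buildDesign(ss, sdmConfig("BRT", "ES", "CPS")),
                   buildDesign(ss, sdmConfig("BRT", "ES", "CPS")))
  ## absent covariates are named in the error
  ss2 <- sampleSet(df, archetype = "CPS", sdmCovariates = c("SST", "MLD2"))
  expect_error(buildDesign(ss2, sdmConfig("GAM", "E", "CPS")), "MLD2")
})

test_that("ensemble enumeration follows roster arithmetic", {
  archs <- c("HMS", "CPS", "GFS"); esms <- paste0("esm", 1:3)
  ens <- enumerateEnsemble(archs, esms)
  expect_equal(nrow(ens), 12 * 3 * 3)  # 15-type roster minus 3 exclusions
  expect_false(any(defaultExclusions() %in% ens$sdmId))
  expect_equal(length(unique(ens$memberId)), nrow(ens))
  ## adding the temperature-only types for the 4 families
  tempRoster <- data.frame(family = c("GAM", "GLMM", "BRT", "MLP"),
                           parameterization = "Temp")
  expect_equal(nrow(enumerateEnsemble(archs, esms, tempRoster,
                                      exclusions = character())), 36)
  ## empty exclusion list over the full 15-type roster
  expect_equal(nrow(enumerateEnsemble(archs, esms,
                                      exclusions = character())), 135)
  ## stable ordering
  expect_identical(ens, enumerateEnsemble(archs, esms))
})

test_that("hurdle fitting rejects degenerate designs", {
  toy <- monotoneToy()
  d <- sampleData(toy)
  allPres <- sampleSet(transform(d, presence = 1, biomass = 2 * SST),
                       sdmCovariates = "SST")
  expect_error(fitHurdle(allPres, sdmConfig("GLMM", "E")), "presences")
  few <- data.frame(year = 1, cell = 1:60, lat = 40, lon = -125,
                    SST = seq(8, 22, length.out = 60),
                    presence = rep(c(1, 0), c(10, 50)))
  few$biomass <- few$presence * 2 * few$SST
  expect_error(fitHurdle(sampleSet(few, sdmCovariates = "SST"),
                         sdmConfig("GLMM", "E")), "positive")
})

test_that("every family recovers a noiseless monotone truth in-sample", {
  toy <- monotoneToy()
  d <- sampleData(toy)
  for (fam in c("GAM", "GLMM", "BRT", "MLP")) {
    fit <- fitHurdle(toy, sdmConfig(fam, "E", "HMS", seed = 3))
    pr <- projectSdm(fit, toy)
    rho <- cor(d$biomass, pr$biomass, method = "spearman")
    expect_gte(rho, 0.99)
  }
})

test_that("duplicating every training row leaves the linear-family fit unchanged", {
  toy <- monotoneToy(n = 400)
  d <- sampleData(toy)
  dup <- d[rep(seq_len(nrow(d)), 2), ]
  dup$cell <- seq_len(nrow(dup))  # keep (year, cell) keys unique
  toy2 <- sampleSet(dup, sdmCovariates = "SST")
  f1 <- fitHurdle(toy, sdmConfig("GLMM", "E", seed = 1))
  f2 <- fitHurdle(toy2, sdmConfig("GLMM", "E", seed = 1))
  p1 <- projectSdm(f1, toy)
  p2 <- projectSdm(f2, toy)
  expect_equal(p1$biomass, p2$biomass, tolerance = 1e-6)
})

test_that("projection applies the bias-corrected lognormal hurdle product", {
  ## constant-information design: occurrence submodel learns the
  ## training presence rate, biomass submodel the training log-mean
  set.seed(10)
  n <- 400
  r <- 0.4
  pres <- rep(c(1, 0), times = c(n * r, n * (1 - r)))
  logb <- rnorm(n * r, 1.2, 0.4)
  d <- data.frame(year = 1, cell = seq_len(n), lat = 40, lon = -125,
                  SST = 15, presence = pres,
                  biomass = c(exp(logb), rep(0, n * (1 - r))))
  ss <- sampleSet(d, sdmCovariates = "SST")
  fit <- fitHurdle(ss, sdmConfig("GLMM", "E", seed = 1))
  pr <- projectSdm(fit, ss)
  s2 <- mean((logb - mean(logb))^2)
  expected <- r * exp(mean(logb) + s2 / 2)
  expect_equal(pr$biomass, rep(expected, n), tolerance = 1e-7)
  expect_equal(fit@sigma2, s2, tolerance = 1e-9)
  ## zero residual variance: combined collapses to p * exp(m)
  d0 <- transform(d, biomass = ifelse(presence == 1, exp(1.2), 0))
  fit0 <- fitHurdle(sampleSet(d0, sdmCovariates = "SST"),
                    sdmConfig("GLMM", "E", seed = 1))
  expect_equal(fit0@sigma2, 0, tolerance = 1e-12)
  expect_equal(projectSdm(fit0, ss)$biomass, rep(r * exp(1.2), n),
               tolerance = 1e-7)
  ## projecting without a required covariate errors by name
  expect_error(projectSdm(fit, d[, setdiff(names(d), "SST")]), "SST")
})

test_that("training ranges are recorded for extrapolation bookkeeping", {
  toy <- monotoneToy(n = 300)
  fit <- fitHurdle(toy, sdmConfig("GLMM", "E", seed = 1))
  d <- sampleData(toy)
  expect_equal(fit@trainRanges["min", "SST"], min(d$SST))
  expect_equal(fit@trainRanges["max", "SST"], max(d$SST))
})
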