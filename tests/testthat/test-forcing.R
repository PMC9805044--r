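test_that("grid geometry: dimensions, coastal bathymetry gradient, determinism", {
  g <- makeGrid(gridSpec(resolution = 1))
  expect_equal(nrow(g), 18 * 18)
  expect_setequal(names(g), c("cell", "lat", "lon", "bathymetry", "coastDist"))
  ## bathymetry deepens away from the coastal (eastern) boundary
  east <- g$bathymetry[g$lon == max(g$lon)]
  west <- g$bathymetry[g$lon == min(g$lon)]
  expect_true(all(east < west))
  for (la in unique(g$lat)) {
    row <- g[g$lat == la, ]
    row <- row[order(row$lon, decreasing = TRUE), ]  # coast -> offshore
    expect_true(all(diff(row$bathymetry) > 0))
  }
  expect_identical(g, makeGrid(gridSpec(resolution = 1)))
  expect_error(gridSpec(resolution = -1), "resolution")
})

test_that("degenerate style yields identical years; linear trend is exact", {
  spec <- tinyGrid(years = 1985:1995)
  env <- generateForcing(spec, flatStyle(), seed = 3)
  for (v in c("SST", "MLD", "ZOO50")) {
    a <- assay(env, v)
    expect_equal(a, a[, rep(1, ncol(a))], ignore_attr = TRUE)
  }
  ## +0.3 C/decade, no noise, no nearshore amplification:
  ## SST(2085) - SST(1985) = 3.0 C at every cell
  spec2 <- gridSpec(resolution = 2, years = seq(1985, 2085, by = 10))
  env2 <- generateForcing(spec2, flatStyle(trends = c(SST = 0.3)), seed = 3)
  sst <- assay(env2, "SST")
  d <- sst[, ncol(sst)] - sst[, 1]
  expect_equal(d, rep(3.0, nrow(sst)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("decadal cycle puts the spectral peak at the configured period", {
  spec <- gridSpec(resolution = 3, years = 1985:2104)  # 120 years, 4 cycles
  style <- esmStyle("cyc", cycleAmp = c(MLD = 5), cyclePeriod = 30,
                    noiseSd = numeric())
  env <- generateForcing(spec, style, seed = 1)
  x <- assay(env, "MLD")[1, ]
  spec_mod <- Mod(fft(x - mean(x)))[2:(length(x) / 2)]
  ## discrete Fourier oracle: peak at 4 cycles / 120 yr = 1/30 yr^-1
  expect_equal(which.max(spec_mod), 4L)
})

test_that("forcing is reproducible and ESMs share grid and year axes", {
  spec <- tinyGrid()
  st <- defaultEsmStyles()[["pseudo-GFDL"]]
  e1 <- generateForcing(spec, st, seed = 11)
  e2 <- generateForcing(spec, st, seed = 11)
  expect_identical(assay(e1, "SST"), assay(e2, "SST"))
  expect_identical(assay(e1, "CHL"), assay(e2, "CHL"))
  e3 <- generateForcing(spec, defaultEsmStyles()[["pseudo-HAD"]], seed = 11)
  expect_identical(gridTable(e1), gridTable(e3))
  expect_identical(envYears(e1), envYears(e3))
  expect_false(identical(assay(e1, "SST"), assay(e3, "SST")))
})

test_that("default pseudo-ESMs diverge through time, most strongly nearshore", {
  spec <- gridSpec(resolution = 1.5, years = 1985:2100)
  envs <- lapply(defaultEsmStyles(), generateForcing, spec = spec, seed = 5)
  yrs <- envYears(envs[[1]])
  early <- which(yrs <= 2010); late <- which(yrs >= 2071)
  for (v in c("SST", "BT", "BO", "MLD", "ZOO50", "ZOO200")) {
    sm <- vapply(envs, function(e) colMeans(assay(e, v)),
                 numeric(length(yrs)))
    spreadOf <- function(rows) mean(apply(sm[rows, , drop = FALSE], 1, sd))
    expect_gt(spreadOf(late), spreadOf(early))
  }
  ## inter-ESM sd averaged over nearshore third vs offshore third
  g <- gridTable(envs[[1]])
  third <- max(g$coastDist) / 3
  near <- g$coastDist <= third
  far <- g$coastDist >= 2 * third
  for (v in c("SST", "BO", "ZOO50")) {
    cube <- vapply(envs, function(e) assay(e, v),
                   matrix(0, nrow(g), length(yrs)))
    sdCell <- apply(cube[, late, ], c(1, 2), sd)
    expect_gte(mean(sdCell[near, ]), mean(sdCell[far, ]))
  }
})

test_that("trend signs and physical bounds hold under noise", {
  styles <- defaultEsmStyles()
  for (st in styles) {
    tr <- st@trendPerDecade
    expect_true(all(tr[c("SST", "BT")] > 0))
    expect_true(all(tr[c("MLD", "BO", "ZOO50", "ZOO200")] < 0))
  }
  ## pairwise trend divergence for BO and ZOO variables
  for (v in c("BO", "ZOO50", "ZOO200")) {
    tv <- vapply(styles, function(s) s@trendPerDecade[[v]], 0)
    expect_true(all(abs(diff(sort(tv))) > 0))
  }
  ## heavy noise cannot break physical bounds
  st <- esmStyle("noisy", trendPerDecade = c(ZOO50 = -1, MLD = -3),
                 noiseSd = c(ZOO50 = 5, MLD = 20, BO = 50, CHL = 2),
                 nearshoreAmp = 1)
  env <- generateForcing(tinyGrid(years = 1985:2040), st, seed = 2)
  expect_true(all(assay(env, "ZOO50") >= 0))
  expect_true(all(assay(env, "BO") >= 0))
  expect_true(all(assay(env, "CHL") >= 0))
  expect_true(all(assay(env, "MLD") > 0))
})

test_that("forcing round-trips through the long-format text file", {
  env <- generateForcing(tinyGrid(years = 1985:1987, resolution = 3),
                         defaultEsmStyles()[[1]], seed = 9)
  path <- tempfile(fileext = ".csv")
  writeForcing(env, path)
  env2 <- readForcing(path, esmId = esmId(env))
  for (v in envVariables(env))
    expect_equal(assay(env2, v), assay(env, v), tolerance = 1e-9,
                 ignore_attr = TRUE)
  expect_equal(gridTable(env2)$bathymetry, gridTable(env)$bathymetry,
               tolerance = 1e-9)
})

test_that("monthly ingest takes the March-May mean and reports absent variables", {
  grid <- data.frame(lat = c(30, 30), lon = c(-120, -119))
  rows <- list()
  for (v in c("SST", "BT", "BO", "MLD", "ZOO50", "ZOO200", "CHL")) {
    for (mo in 1:6) {
      val <- if (v == "SST" && mo %in% 3:5) c(10, 12, 14)[mo - 2] else 5
      rows[[paste(v, mo)]] <- data.frame(variable = v, year = 2000, month = mo,
                                         lat = grid$lat, lon = grid$lon,
                                         value = val)
    }
  }
  rows$bat <- data.frame(variable = "bathymetry", year = NA, month = NA,
                         lat = grid$lat, lon = grid$lon, value = c(100, 900))
  tab <- do.call(rbind, rows)
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  env <- readForcing(path)
  expect_equal(as.vector(assay(env, "SST")), c(12, 12))  # mean(10, 12, 14)
  ## a file without BO must name the missing variable
  write.csv(tab[tab$variable != "BO", ], path, row.names = FALSE)
  expect_error(readForcing(path), "BO")
})
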