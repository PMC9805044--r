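## End-to-end experiment driver: forcing -> operating models -> sampling
## -> ensemble fitting & projection -> evaluation -> novelty -> variance
## partitioning, from a single validated configuration with derived
## per-stage seeds and optional content-hash stage memoization.

#' Build and validate an experiment configuration
#'
#' @param grid a \linkS4class{GridSpec} covering training and test years.
#' @param styles named list of \linkS4class{EsmStyle} (the pseudo-ESMs).
#' @param archetypes character vector naming which archetypes to run.
#' @param archetypeSpecs named list of \linkS4class{ArchetypeSpec}
#'   definitions that \code{archetypes} must resolve against.
#' @param roster SDM-type roster (data.frame family, parameterization).
#' @param exclusions "FAMILY_PARAM" ids excluded from the retained
#'   ensemble.
#' @param tempOnly also run the temperature-only experiment (the same
#'   retained roster with the environmental covariates collapsed to the
#'   archetype's single temperature covariate).
#' @param trainYears,testYears fitting and projection year ranges.
#' @param nPerYear random cells sampled per year (the observation
#'   design; 500 by default).
#' @param smoothWindow odd running-mean window for reported series.
#' @param masterSeed integer master seed; all stage seeds derive from it.
#' @return A validated list of class "ExperimentConfig".
#' @export
experimentConfig <- function(grid = gridSpec(),
                             styles = defaultEsmStyles(),
                             archetypes = c("HMS", "CPS", "GFS"),
                             archetypeSpecs = defaultArchetypes(),
                             roster = defaultRoster(),
                             exclusions = defaultExclusions(),
                             tempOnly = TRUE,
                             trainYears = 1985:2010,
                             testYears = 2011:2100,
                             nPerYear = 500,
                             smoothWindow = 11,
                             masterSeed = 1L) {
  stopifnot(is(grid, "GridSpec"))
  validObject(grid)
  unknown <- setdiff(archetypes, names(archetypeSpecs))
  if (length(unknown))
    stop("unknown archetype name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stopIfNot(all(vapply(styles, is, TRUE, "EsmStyle")),
            "styles must be EsmStyle objects")
  stopIfNot(all(c(trainYears, testYears) %in% grid@years),
            "train/test years must lie within the grid's year axis")
  stopIfNot(smoothWindow %% 2 == 1, "smoothWindow must be odd")
  stopIfNot(nPerYear >= 1, "nPerYear must be >= 1")
  cfg <- list(grid = grid, styles = styles, archetypes = archetypes,
              archetypeSpecs = archetypeSpecs[archetypes], roster = roster,
              exclusions = exclusions, tempOnly = tempOnly,
              trainYears = as.integer(trainYears),
              testYears = as.integer(testYears),
              nPerYear = nPerYear, smoothWindow = smoothWindow,
              masterSeed = as.integer(masterSeed))
  class(cfg) <- "ExperimentConfig"
  cfg
}

## run one stage with optional RDS memoization keyed by config + stage
withStage <- function(name, cacheDir, cfgHash, manifest, fun, verbose) {
  t0 <- proc.time()[["elapsed"]]
  cached <- FALSE
  path <- if (!is.null(cacheDir))
    file.path(cacheDir, paste0(name, "-", cfgHash, ".rds")) else NULL
  if (!is.null(path) && file.exists(path)) {
    out <- readRDS(path)
    cached <- TRUE
  } else {
    out <- fun()
    if (!is.null(path)) {
      dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(out, path)
    }
  }
  el <- proc.time()[["elapsed"]] - t0
  if (verbose) message(sprintf("[%s] %s (%.1fs)", name,
                               if (cached) "cached" else "computed", el))
  manifest$stages[[name]] <- list(cached = cached, seconds = el)
  out
}

## fit one ensemble member and reduce it to summary tables
fitMember <- function(member, experiment, trainS, testS, cfg) {
  arch <- member$archetype
  if (experiment == "temp") {
    tv <- tempVariable(arch)
    trainS@sdmCovariates <- tv
    testS@sdmCovariates <- tv
  }
  config <- sdmConfig(member$family, member$parameterization, arch,
                      seed = childSeed(cfg$masterSeed, "fit", experiment,
                                       member$memberId))
  fit <- fitHurdle(trainS, config)
  predTrain <- projectSdm(fit, trainS)
  predTest <- projectSdm(fit, testS)

  dtr <- sampleData(trainS); dte <- sampleData(testS)
  meta <- data.frame(experiment = experiment, archetype = arch,
                     esm = member$esm, family = member$family,
                     parameterization = member$parameterization,
                     sdmId = member$sdmId, memberId = member$memberId)
  ## pooled in-sample statistics
  fitStats <- cbind(meta,
    trainRho = cor(dtr$biomass, predTrain$biomass, method = "spearman"),
    trainAuc = aucMW(dtr$presence, predTrain$pOcc))
  ## annual test-period skill
  rhoT <- spearmanByYear(dtr[, c("year", "cell", "biomass")], predTrain)
  rhoP <- spearmanByYear(dte[, c("year", "cell", "biomass")], predTest)
  aucP <- aucByYear(dte[, c("year", "cell", "presence")], predTest)
  perf <- cbind(meta[rep(1, nrow(rhoT) + nrow(rhoP)), ],
                rbind(cbind(role = "train", rhoT, auc = NA_real_),
                      cbind(role = "test", rhoP, auc = aucP$auc)))
  ## regional aggregates of projected biomass (dominance input)
  regs <- regionalTag(dte$lat)
  agg <- aggregate(list(biomass = predTest$biomass),
                   by = list(year = predTest$year, region = regs), sum)
  agg <- cbind(meta[rep(1, nrow(agg)), ], agg)
  rownames(perf) <- rownames(agg) <- NULL
  list(fitStats = fitStats, perf = perf, agg = agg)
}

#' Run the full simulation experiment
#'
#' Executes every stage for every (archetype, pseudo-ESM, ensemble
#' member): forcing generation, operating-model truth, the annual
#' sampling design, hurdle-SDM fitting and projection, annual skill
#' scoring, environmental-novelty accounting, and dominance-based
#' uncertainty partitioning (for the full-covariate and, optionally,
#' temperature-only experiments).  With a \code{cacheDir}, completed
#' stages are memoized by a content hash of the configuration and
#' re-runs load them instead of recomputing.
#'
#' @param cfg an [experimentConfig()].
#' @param cacheDir optional directory for stage memoization.
#' @param verbose print stage progress.
#' @return A list of class "ExperimentResult" with elements
#'   \code{env}, \code{truth}, \code{members}, \code{fitStats},
#'   \code{perf}, \code{agg}, \code{novelty}, \code{shares},
#'   \code{spread}, \code{manifest}, \code{config}.
#' @export
runExperiment <- function(cfg, cacheDir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  cfgHash <- contentHash(cfg)
  manifest <- new.env()
  manifest$stages <- list()
  esms <- names(cfg$styles)
  seed <- cfg$masterSeed

  env <- withStage("forcing", cacheDir, cfgHash, manifest, function() {
    lapply(cfg$styles, function(st) generateForcing(cfg$grid, st, seed))
  }, verbose)

  truth <- withStage("truth", cacheDir, cfgHash, manifest, function() {
    out <- list()
    for (a in cfg$archetypes) for (e in esms)
      out[[paste(a, e, sep = ".")]] <-
        drawTruth(env[[e]], cfg$archetypeSpecs[[a]], seed)
    out
  }, verbose)

  samples <- withStage("samples", cacheDir, cfgHash, manifest, function() {
    out <- list()
    for (a in cfg$archetypes) for (e in esms) {
      tr <- sampleCells(truth[[paste(a, e, sep = ".")]], env[[e]],
                        cfg$trainYears, cfg$nPerYear, seed, role = "train")
      te <- sampleCells(truth[[paste(a, e, sep = ".")]], env[[e]],
                        cfg$testYears, cfg$nPerYear, seed, role = "test")
      out[[paste(a, e, sep = ".")]] <-
        list(train = attachProxyCovariates(tr),
             test = attachProxyCovariates(te))
    }
    out
  }, verbose)

  members <- enumerateEnsemble(cfg$archetypes, esms, cfg$roster,
                               cfg$exclusions)
  experiments <- c("full", if (cfg$tempOnly) "temp")

  fitOut <- withStage("fits", cacheDir, cfgHash, manifest, function() {
    res <- list()
    for (ex in experiments) for (i in seq_len(nrow(members))) {
      mem <- members[i, ]
      key <- paste(mem$archetype, mem$esm, sep = ".")
      res[[paste(ex, mem$memberId)]] <-
        fitMember(mem, ex, samples[[key]]$train, samples[[key]]$test, cfg)
      if (verbose && i %% 12 == 0)
        message("  fitted ", ex, " ", key, " (", i, "/", nrow(members), ")")
    }
    list(fitStats = do.call(rbind, lapply(res, `[[`, "fitStats")),
         perf = do.call(rbind, lapply(res, `[[`, "perf")),
         agg = do.call(rbind, lapply(res, `[[`, "agg")))
  }, verbose)

  novelty <- withStage("novelty", cacheDir, cfgHash, manifest, function() {
    out <- list()
    for (a in cfg$archetypes) for (e in esms) {
      spec <- cfg$archetypeSpecs[[a]]
      g <- gridTable(env[[e]])
      cells <- g$cell[g$bathymetry <= spec@maxDepth]
      ref <- buildReference(env[[e]], noveltyCovariates(a), cfg$trainYears,
                            cells = cells)
      pn <- percentNovel(env[[e]], ref, cells = cells)
      out[[paste(a, e, sep = ".")]] <- cbind(archetype = a, esm = e, pn)
    }
    do.call(rbind, out)
  }, verbose)

  shares <- withStage("shares", cacheDir, cfgHash, manifest, function() {
    out <- list()
    for (ex in experiments) for (a in cfg$archetypes) {
      agg <- fitOut$agg
      agg <- agg[agg$experiment == ex & agg$archetype == a, ]
      sh <- dominanceShares(agg)
      sh <- sh[order(sh$region, sh$year), ]
      for (cn in c("shareEsm", "shareType", "shareParam")) {
        sm <- paste0(cn, "Smooth")
        sh[[sm]] <- NA_real_
        for (r in unique(sh$region)) {
          k <- sh$region == r
          sh[[sm]][k] <- runningMean(sh[[cn]][k], cfg$smoothWindow)
        }
      }
      out[[paste(ex, a)]] <- cbind(experiment = ex, archetype = a, sh)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }, verbose)

  ## ensemble spread of annual test-period skill (full experiment)
  perfTest <- fitOut$perf[fitOut$perf$role == "test" &
                            fitOut$perf$experiment == "full", ]
  spread <- do.call(rbind, lapply(split(
    perfTest, list(perfTest$archetype, perfTest$esm), drop = TRUE),
    function(s) {
      sp <- ensembleSpread(data.frame(year = s$year, member = s$memberId,
                                      value = s$rho))
      cbind(archetype = s$archetype[1], esm = s$esm[1], sp)
    }))
  rownames(spread) <- NULL

  res <- list(config = cfg, env = env, truth = truth, members = members,
              fitStats = fitOut$fitStats, perf = fitOut$perf,
              agg = fitOut$agg,
              novelty = novelty, shares = shares, spread = spread,
              manifest = list(configHash = cfgHash,
                              stages = manifest$stages,
                              masterSeed = seed))
  class(res) <- "ExperimentResult"
  res
}

#' Headline summary of an experiment
#'
#' Collects the study's headline quantities from a completed run: the
#' retained-ensemble training fit, projection-skill decay between early
#' (2011--2040) and late (2071--2100) windows, end-of-century
#' environmental novelty, the novelty-skill coupling, and the early/late
#' uncertainty partitioning for both experiments.
#'
#' @param res an "ExperimentResult" from [runExperiment()].
#' @param earlyYears,lateYears projection windows compared throughout.
#' @return A nested list (JSON-serializable).
#' @export
summarizeExperiment <- function(res, earlyYears = 2011:2040,
                                lateYears = 2071:2100) {
  stopifnot(inherits(res, "ExperimentResult"))
  fs <- res$fitStats
  full <- fs[fs$experiment == "full", ]
  perf <- res$perf[res$perf$experiment == "full" & res$perf$role == "test", ]

  meanRhoWindow <- function(a, yrs) {
    s <- perf[perf$archetype == a & perf$year %in% yrs, ]
    mean(tapply(s$rho, s$year, mean, na.rm = TRUE), na.rm = TRUE)
  }
  archs <- unique(full$archetype)
  decay <- lapply(setNames(archs, archs), function(a)
    list(rhoEarly = meanRhoWindow(a, earlyYears),
         rhoLate = meanRhoWindow(a, lateYears)))

  nov <- res$novelty
  nov2100 <- vapply(setNames(archs, archs), function(a)
    mean(nov$percentNovel[nov$archetype == a &
                            nov$year == max(nov$year)]), 0)

  ## year-wise coupling between ensemble-mean skill and percent novelty
  em <- aggregate(rho ~ archetype + esm + year, perf, mean, na.rm = TRUE)
  cp <- merge(em, nov, by = c("archetype", "esm", "year"))
  noveltyRhoCor <- cor(cp$percentNovel, cp$rho, method = "spearman",
                       use = "complete.obs")

  shareWindow <- function(ex, yrs) {
    s <- res$shares[res$shares$experiment == ex & res$shares$year %in% yrs, ]
    c(esm = mean(s$shareEsmSmooth, na.rm = TRUE),
      type = mean(s$shareTypeSmooth, na.rm = TRUE),
      param = mean(s$shareParamSmooth, na.rm = TRUE))
  }
  shares <- list(full = list(early = shareWindow("full", earlyYears),
                             late = shareWindow("full", lateYears)))
  if (any(res$shares$experiment == "temp"))
    shares$temp <- list(early = shareWindow("temp", earlyYears),
                        late = shareWindow("temp", lateYears))

  cps <- full[full$archetype == "CPS" & full$parameterization == "E", ]
  list(
    ensembleSize = length(unique(res$members$sdmId)),
    nMembers = nrow(res$members),
    trainRhoMin = min(full$trainRho),
    trainAucRange = range(full$trainAuc),
    cpsOccAucBest = if (nrow(cps)) max(cps$trainAuc) else NA_real_,
    skillDecay = decay,
    percentNovelFinal = as.list(nov2100),
    noveltyRhoCor = noveltyRhoCor,
    uncertaintyShares = shares)
}
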