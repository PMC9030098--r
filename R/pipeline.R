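#' Default pipeline configuration
#'
#' All thresholds of the workflow live here: collinearity cutoffs
#' (`rhoMax = 0.7`, `vifMax = 10`), thinning distance, minimum records per
#' species (3), pseudo-absence distance (5.5 km), the 80:20 spatial-block
#' splits, the ensemble admission gate (`tssMin = 0.8`), the hotspot
#' quantile (0.99) and the dispersal assumption. Every stochastic stage
#' draws its seed deterministically from `masterSeed`.
#'
#' @param masterSeed master integer seed.
#' @param ... overrides for any default field.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(masterSeed = 1, ...) {
  cfg <- list(
    masterSeed = as.integer(masterSeed),
    gridShape = c(150, 150),
    nIslands = 5,
    cellKm = 1,
    nSpecies = 12,
    nRecords = 300,
    biasStrength = 0.05,
    paCoverage = 0.28,
    rhoMax = 0.7,
    vifMax = 10,
    collinearitySamples = 5000,
    keepPredictors = c("bio1", "bio12"),
    thinDistKm = NULL,          # default: grid cell diagonal
    minRecords = 3,
    paMinDistKm = 5.5,
    nPaSets = 2,
    nPerSet = NULL,             # default: min(1000, 10 x presences)
    nFolds = 5,
    nRepeats = 2,
    learner = "rf",
    nTrees = 150,
    tssMin = 0.8,
    hotspotQuantile = 0.99,
    dispersalMode = "buffered",
    bufferKm = 2,
    ghmBreaks = c(0.1, 0.4, 0.7),
    scenarios = list(gcms = "ccsm4-like", rcps = c("rcp45", "rcp85"),
                     slices = c("2020s", "2050s", "2080s")),
    nShiftPerm = 499)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Small demonstration configuration
#'
#' A 70 x 70 grid with 6 virtual species and one GCM, sized so the full
#' pipeline completes in about a minute.
#'
#' @param masterSeed master integer seed.
#' @param ... further overrides.
#' @return `PipelineConfig`.
#' @export
demoConfig <- function(masterSeed = 1, ...) {
  pipelineConfig(masterSeed,
                 gridShape = c(70, 70), nIslands = 4, nSpecies = 6,
                 nRecords = 200, nPaSets = 1, nRepeats = 1, nTrees = 80,
                 collinearitySamples = 2000, nShiftPerm = 199, ...)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param file YAML path.
#' @param config a `PipelineConfig`.
#' @return `readConfig` returns a `PipelineConfig`.
#' @export
readConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(pipelineConfig, c(list(masterSeed = cfg$masterSeed),
                            cfg[setdiff(names(cfg), "masterSeed")]))
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

# deterministic per-stage seed expansion (kept well below 2^31)
stageSeed <- function(masterSeed, stage, k = 0L) {
  (as.integer(masterSeed) * 1009L + match(stage,
    c("synth", "predictors", "occurrences", "fit", "project", "hotspots",
      "overlap", "report")) * 7927L + as.integer(k) * 13L) %% 1000000007L
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

readManifest <- function(runDir) {
  f <- file.path(runDir, "manifest.json")
  if (!file.exists(f)) return(list(stages = list()))
  jsonlite::read_json(f)
}

writeManifest <- function(runDir, manifest) {
  jsonlite::write_json(manifest, file.path(runDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

stageDone <- function(manifest, stage, hash)
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$status, "done") &&
    identical(manifest$stages[[stage]]$configHash, hash)

# derive the full candidate predictor stack from a climate set and DEM
derivePredictors <- function(clim, arch) {
  combineStacks(deriveBioclim(clim), deriveEnvirem(clim),
                deriveTopographic(arch@dem))
}

#' Run the full analysis pipeline
#'
#' Stages: `synth` (archipelago, climate, virtual species, occurrences,
#' protected areas, human modification), `predictors` (bioclim + PET +
#' topographic stacks per scenario, collinearity filtering), `occurrences`
#' (dedupe, thin, minimum-record filter, accessibility-bias model), `fit`
#' (per-species ESMs with the TSS admission gate), `project` (projection,
#' clamping, maxSSS binarization, range change, ExDet analogue fractions),
#' `hotspots` (SR/CWE surfaces, L1 hotspots, shift tests, human-impact
#' contrast), `overlap` (protected-area overlap and trend) and `report`.
#' Completed stages are skipped on rerun unless `force`; per-stage status,
#' seeds and the configuration hash are recorded in `manifest.json`.
#'
#' @param config a `PipelineConfig`.
#' @param runDir output directory.
#' @param force rerun stages even when cached.
#' @param stages subset of stages to run (dependencies must exist).
#' @param quiet suppress progress messages.
#' @return `runDir`, invisibly; results live in per-stage `.rds` files and
#'   plain-text tables under `runDir`.
#' @export
runPipeline <- function(config, runDir, force = FALSE,
                        stages = c("synth", "predictors", "occurrences",
                                   "fit", "project", "hotspots", "overlap",
                                   "report"),
                        quiet = FALSE) {
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  manifest <- readManifest(runDir)
  manifest$configHash <- hash
  writeConfig(config, file.path(runDir, "config.yaml"))
  say <- function(...) if (!quiet) message(sprintf(...))
  mark <- function(stage, status, extra = list()) {
    manifest$stages[[stage]] <<- c(list(status = status, configHash = hash,
                                        time = format(Sys.time())), extra)
    writeManifest(runDir, manifest)
  }
  store <- function(name, obj) saveRDS(obj, file.path(runDir, paste0(name, ".rds")))
  fetch <- function(name) readRDS(file.path(runDir, paste0(name, ".rds")))
  runStage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    if (!force && stageDone(manifest, stage, hash)) {
      say("stage %s: cached", stage)
      return(invisible(NULL))
    }
    say("stage %s: running", stage)
    tryCatch({
      fun()
      mark(stage, "done", list(seed = stageSeed(config$masterSeed, stage)))
    }, error = function(e) {
      mark(stage, "failed", list(error = conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    invisible(NULL)
  }

  allScen <- expand.grid(gcm = config$scenarios$gcms,
                         rcp = config$scenarios$rcps,
                         slice = config$scenarios$slices,
                         stringsAsFactors = FALSE)
  scenList <- lapply(seq_len(nrow(allScen)), function(i)
    scenarioSpec(allScen$gcm[i], allScen$rcp[i], allScen$slice[i]))
  scenKey <- vapply(scenList, format, "")

  runStage("synth", function() {
    s <- stageSeed(config$masterSeed, "synth")
    arch <- makeArchipelago(s, nIslands = config$nIslands,
                            gridShape = config$gridShape,
                            cellKm = config$cellKm)
    clim <- makeMonthlyClimate(arch, seed = s + 1L)
    bio <- deriveBioclim(clim)
    pool <- defaultVirtualSpecies(bio)[seq_len(config$nSpecies)]
    occ <- NULL; truth <- list()
    for (i in seq_along(pool)) {
      vs <- pool[[i]]
      samp <- sampleVirtualOccurrences(vs, bio, arch, config$nRecords,
                                       biasStrength = config$biasStrength,
                                       seed = s + 100L + i)
      occ <- rbind(occ, samp$occurrences)
      truth[[vs@name]] <- samp$suitability
    }
    pa <- makeProtectedAreas(arch, config$paCoverage, seed = s + 2L)
    ghm <- makeHumanModification(arch, seed = s + 3L)
    store("arch", arch); store("climBaseline", clim)
    store("species", pool); store("truth", truth); store("pa", pa)
    store("ghm", ghm)
    writeOccurrences(occ, file.path(runDir, "occurrences_raw.csv"))
    writeGeoJSON(pa, file.path(runDir, "protected_areas.geojson"))
  })

  runStage("predictors", function() {
    arch <- fetch("arch"); clim <- fetch("climBaseline")
    base <- derivePredictors(clim, arch)
    rep <- filterCollinear(base, samples = config$collinearitySamples,
                           rhoMax = config$rhoMax, vifMax = config$vifMax,
                           keep = config$keepPredictors,
                           seed = stageSeed(config$masterSeed, "predictors"))
    jsonlite::write_json(list(retained = rep$retained,
                              dropped = rep$dropped),
                         file.path(runDir, "collinearity.json"),
                         auto_unbox = TRUE, dataframe = "rows")
    futures <- list()
    for (i in seq_along(scenList)) {
      d <- scenarioDelta(scenList[[i]])
      climF <- applyScenario(clim, d$deltaT, d$precFactor, scenList[[i]])
      futures[[scenKey[i]]] <- derivePredictors(climF, arch)
    }
    store("stackBaseline", base); store("collinearity", rep)
    store("stackFutures", futures)
  })

  runStage("occurrences", function() {
    arch <- fetch("arch")
    occ <- readOccurrences(file.path(runDir, "occurrences_raw.csv"))
    s <- stageSeed(config$masterSeed, "occurrences")
    thinDist <- if (is.null(config$thinDistKm))
      sqrt(2) * config$cellKm else config$thinDistKm
    occ <- dedupeOccurrences(occ, arch@dem)
    occ <- thinOccurrences(occ, thinDist, seed = s)
    flt <- filterMinRecords(occ, config$minRecords)
    writeOccurrences(flt$occurrences,
                     file.path(runDir, "occurrences_clean.csv"))
    dset <- distanceToPoints(arch@dem, arch@settlements)
    bias <- fitBiasModel(flt$occurrences,
                         layerStack(list(settlements = dset)), arch@dem)
    writeBiasModel(bias, file.path(runDir, "bias_model.json"))
    store("occClean", flt$occurrences)
    store("droppedSpecies", flt$droppedSpecies)
    store("bias", bias)
  })

  runStage("fit", function() {
    arch <- fetch("arch")
    occ <- fetch("occClean")
    base <- fetch("stackBaseline")
    rep <- fetch("collinearity")
    retained <- subsetStack(base, rep$retained)
    blockKm <- tryCatch(
      as.numeric(medianAutocorrelationRange(
        retained, seed = stageSeed(config$masterSeed, "fit"))),
      error = function(e) config$paMinDistKm)
    ensembles <- list(); ensemblesAll <- list(); evalRows <- NULL
    for (sp in unique(occ$species)) {
      s <- stageSeed(config$masterSeed, "fit", match(sp, unique(occ$species)))
      pres <- occ[occ$species == sp, ]
      nPer <- if (is.null(config$nPerSet)) min(1000, 10 * nrow(pres))
              else config$nPerSet
      pa <- tryCatch(
        suppressWarnings(
          generatePseudoAbsences(sp, occ, arch@dem,
                                 minDist = config$paMinDistKm,
                                 nSets = config$nPaSets, nPerSet = nPer,
                                 seed = s, allowFewer = TRUE)),
        error = function(e) NULL)
      if (is.null(pa)) {
        evalRows <- rbind(evalRows, data.frame(
          species = sp, nPresence = nrow(pres), ensembleTss = NA,
          auc = NA, aucPr = NA, cbi = NA, ece = NA, admitted = FALSE))
        next
      }
      ens <- suppressWarnings(
        fitEsm(sp, pres, pa, retained, blockSizeKm = max(blockKm, 2),
               nFolds = config$nFolds, nRepeats = config$nRepeats,
               learner = config$learner, nTrees = config$nTrees,
               tssMin = config$tssMin, seed = s))
      ev <- if (nrow(ens@cvPred))
        evaluateScores(ens@cvPred$pred, ens@cvPred$label) else NULL
      evalRows <- rbind(evalRows, data.frame(
        species = sp, nPresence = nrow(pres),
        ensembleTss = ens@ensembleTss,
        auc = if (is.null(ev)) NA else ev$auc,
        aucPr = if (is.null(ev)) NA else ev$aucPr,
        cbi = if (is.null(ev)) NA else ev$cbi,
        ece = if (is.null(ev)) NA else ev$ece,
        admitted = !is.na(ens@ensembleTss) && ens@ensembleTss >= config$tssMin))
      ensemblesAll[[sp]] <- ens
      if (!is.na(ens@ensembleTss) && ens@ensembleTss >= config$tssMin)
        ensembles[[sp]] <- ens
    }
    write.csv(evalRows, file.path(runDir, "evaluation.csv"),
              row.names = FALSE)
    store("ensembles", ensembles); store("ensemblesAll", ensemblesAll)
    store("evalTable", evalRows)
    store("blockKm", blockKm)
  })

  runStage("project", function() {
    base <- fetch("stackBaseline")
    futures <- fetch("stackFutures")
    rep <- fetch("collinearity")
    ensembles <- fetch("ensembles")
    retainedNames <- rep$retained
    rangeRows <- NULL
    currentRanges <- list(); futureRanges <- list()
    for (sp in names(ensembles)) {
      ens <- ensembles[[sp]]
      suitC <- projectEnsemble(ens, base)
      clampC <- clampSuitability(ens, base, suitC)
      curMap <- binarizeSuitability(clampC$suitability, ens@threshold, sp,
                                    "current")
      currentRanges[[sp]] <- curMap
      for (key in names(futures)) {
        suitF <- projectEnsemble(ens, futures[[key]])
        clampF <- clampSuitability(ens, futures[[key]], suitF)
        futMap <- binarizeSuitability(clampF$suitability, ens@threshold, sp,
                                      key)
        futureRanges[[paste(sp, key, sep = "@")]] <- futMap
        rc <- rangeChange(curMap, futMap,
                          dispersalMode = config$dispersalMode,
                          bufferKm = config$bufferKm)
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        rangeRows <- rbind(rangeRows, data.frame(
          species = sp, gcm = parts[1], rcp = parts[2], slice = parts[3],
          dispersalMode = rc$dispersalMode, currentCells = rc$currentCells,
          lossCells = rc$lossCells, gainCells = rc$gainCells,
          stableCells = rc$stableCells, changePct = rc$changePct))
      }
    }
    analogueRows <- NULL
    for (key in names(futures)) {
      ex <- exDetStacks(subsetStack(base, retainedNames),
                        subsetStack(futures[[key]], retainedNames),
                        maxRef = 1000,
                        seed = stageSeed(config$masterSeed, "project"))
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      analogueRows <- rbind(analogueRows, data.frame(
        gcm = parts[1], rcp = parts[2], slice = parts[3],
        analogueFraction = ex$analogueFraction,
        meanPctNearby = mean(ex$pctNearby)))
    }
    write.csv(rangeRows, file.path(runDir, "range_change.csv"),
              row.names = FALSE)
    write.csv(analogueRows, file.path(runDir, "analogue_climate.csv"),
              row.names = FALSE)
    store("currentRanges", currentRanges)
    store("futureRanges", futureRanges)
    store("rangeTable", rangeRows)
    store("analogueTable", analogueRows)
  })

  runStage("hotspots", function() {
    arch <- fetch("arch")
    ghm <- fetch("ghm")
    currentRanges <- fetch("currentRanges")
    futureRanges <- fetch("futureRanges")
    s <- stageSeed(config$masterSeed, "hotspots")
    divC <- stackDiversity(currentRanges, "current")
    hsC <- list(SR = l1Hotspots(divC$sr, config$hotspotQuantile, arch@dem,
                                "SR", "current"),
                CWE = l1Hotspots(divC$cwe, config$hotspotQuantile, arch@dem,
                                 "CWE", "current"))
    divF <- list(); hsF <- list(); shiftRows <- NULL
    for (key in scenKey) {
      maps <- futureRanges[endsWith(names(futureRanges), paste0("@", key))]
      maps <- Filter(function(m) sum(m$presence@values, na.rm = TRUE) > 0,
                     maps)
      if (length(maps) < 1) next
      dv <- suppressWarnings(stackDiversity(maps, key))
      divF[[key]] <- dv
      for (metric in c("SR", "CWE")) {
        map <- if (metric == "SR") dv$sr else dv$cwe
        hs <- tryCatch(l1Hotspots(map, config$hotspotQuantile, arch@dem,
                                  metric, key), error = function(e) NULL)
        if (is.null(hs)) next
        hsF[[paste(metric, key, sep = "@")]] <- hs
        st <- shiftTests(hsC[[metric]], hs, nPerm = config$nShiftPerm,
                         seed = s)
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        shiftRows <- rbind(shiftRows, data.frame(
          metric = metric, gcm = parts[1], rcp = parts[2], slice = parts[3],
          kwH = st$kwH, kwP = st$kwP, watsonU2 = st$watsonU2,
          watsonP = st$watsonP,
          dAltM = st$meanAltFuture - st$meanAltCurrent,
          dLat = st$centroidFuture["lat"] - st$centroidCurrent["lat"]))
      }
    }
    hmc <- humanModContrast(divC, ghm, config$ghmBreaks)
    write.csv(shiftRows, file.path(runDir, "shift_tests.csv"),
              row.names = FALSE)
    store("divCurrent", divC); store("divFutures", divF)
    store("hotspotsCurrent", hsC); store("hotspotsFutures", hsF)
    store("shiftTable", shiftRows); store("humanModContrast", hmc)
    writeHotspots(hsC$SR, file.path(runDir, "hotspots_SR_current"))
    writeHotspots(hsC$CWE, file.path(runDir, "hotspots_CWE_current"))
  })

  runStage("overlap", function() {
    arch <- fetch("arch")
    pa <- fetch("pa")
    hsC <- fetch("hotspotsCurrent")
    hsF <- fetch("hotspotsFutures")
    paMask <- rasterizePa(pa, arch@dem)
    all <- c(list(hsC$SR, hsC$CWE), unname(hsF))
    tab <- overlapTable(all, paMask)
    write.csv(tab, file.path(runDir, "pa_overlap.csv"), row.names = FALSE)
    store("paMask", paMask); store("overlapTable", tab)
    jsonlite::write_json(as.list(attr(tab, "trend")),
                         file.path(runDir, "pa_overlap_trend.json"),
                         auto_unbox = TRUE)
  })

  runStage("report", function() {
    reportRun(runDir, file.path(runDir, "report.md"))
  })

  invisible(runDir)
}

#' Summarize a pipeline run
#'
#' Collates the per-species range-change table, analogue-climate fractions,
#' hotspot counts, shift tests and the protected-area overlap trend into a
#' markdown document; missing stages are flagged rather than failing.
#'
#' @param runDir a run directory produced by [runPipeline()].
#' @param file output path (default `report.md` inside `runDir`).
#' @return the report path, invisibly.
#' @export
reportRun <- function(runDir, file = file.path(runDir, "report.md")) {
  has <- function(name) file.exists(file.path(runDir, paste0(name, ".rds")))
  fetch <- function(name) readRDS(file.path(runDir, paste0(name, ".rds")))
  lines <- c("# Pipeline run report", "")
  if (has("evalTable")) {
    ev <- fetch("evalTable")
    lines <- c(lines, sprintf(
      "Modelled species: %d of %d admitted (ensemble TSS >= gate).",
      sum(ev$admitted, na.rm = TRUE), nrow(ev)), "")
  } else lines <- c(lines, "(fit stage missing)", "")
  if (has("rangeTable")) {
    rt <- fetch("rangeTable")
    lines <- c(lines, "## Range change (% per species x scenario)", "",
               "species | gcm | rcp | slice | change%",
               "--- | --- | --- | --- | ---",
               sprintf("%s | %s | %s | %s | %.1f", rt$species, rt$gcm,
                       rt$rcp, rt$slice, rt$changePct), "")
  } else lines <- c(lines, "(project stage missing)", "")
  if (has("analogueTable")) {
    at <- fetch("analogueTable")
    lines <- c(lines, "## Analogue climate fraction (%)", "",
               sprintf("- %s %s %s: %.2f%%", at$gcm, at$rcp, at$slice,
                       at$analogueFraction), "")
  }
  if (has("shiftTable")) {
    st <- fetch("shiftTable")
    if (!is.null(st) && nrow(st))
      lines <- c(lines, "## Hotspot shifts", "",
                 sprintf("- %s %s %s %s: KW H = %.2f (p = %.3g), Watson U2 = %.3g (p = %.3g), dAlt = %.0f m",
                         st$metric, st$gcm, st$rcp, st$slice, st$kwH, st$kwP,
                         st$watsonU2, st$watsonP, st$dAltM), "")
  }
  if (has("overlapTable")) {
    ot <- fetch("overlapTable")
    tr <- attr(ot, "trend")
    lines <- c(lines, "## Protected-area overlap", "",
               sprintf("- %s (%s): %.1f%% of hotspot cells inside PAs",
                       ot$metric, ot$scenario, ot$fraction), "",
               sprintf("Trend across slices: %s",
                       paste(sprintf("%s %s", names(tr), tr),
                             collapse = "; ")), "")
  } else lines <- c(lines, "(overlap stage missing)", "")
  writeLines(lines, file)
  invisible(file)
}
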