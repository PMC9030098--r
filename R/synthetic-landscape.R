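# Gaussian random field on a torus via FFT smoothing of white noise.
# Returns a standardized (mean 0, sd 1) matrix. Consumes the RNG stream.
smoothField <- function(nr, nc, rangeCells) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (rangeCells <= 0) return((z - mean(z)) / sd(z))
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  d2 <- outer(di^2, dj^2, `+`)
  k <- exp(-d2 / (2 * rangeCells^2))
  sm <- Re(fft(fft(z) * fft(k), inverse = TRUE)) / length(z)
  (sm - mean(sm)) / sd(sm)
}

# Connected components of a logical mask (4-neighbour), via igraph.
# Returns an integer matrix: component id on TRUE cells, NA elsewhere,
# components numbered by decreasing size.
maskComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(NA_integer_, nr, nc))
  id <- matrix(NA_integer_, nr, nc)
  id[idx] <- seq_along(idx)
  edges <- NULL
  right <- which(mask[, -nc] & mask[, -1])
  if (length(right)) {
    r <- ((right - 1) %% nr) + 1; cl <- ((right - 1) %/% nr) + 1
    edges <- rbind(edges, cbind(id[cbind(r, cl)], id[cbind(r, cl + 1)]))
  }
  down <- which(mask[-nr, ] & mask[-1, ])
  if (length(down)) {
    r <- ((down - 1) %% (nr - 1)) + 1; cl <- ((down - 1) %/% (nr - 1)) + 1
    edges <- rbind(edges, cbind(id[cbind(r, cl)], id[cbind(r + 1, cl)]))
  }
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  out <- matrix(NA_integer_, nr, nc)
  out[idx] <- relabel[comp$membership]
  out
}

#' Generate a synthetic archipelago
#'
#' Builds a DEM as a sum of island-shaped radial bumps plus a smoothed random
#' field, thresholds it at sea level to obtain a multi-island land mask, and
#' places one settlement per island (plus extras on the largest islands).
#' Identical arguments and seed give bit-identical output.
#'
#' @param seed integer seed.
#' @param nIslands target number of islands (land components).
#' @param gridShape integer `(rows, cols)`, at least 50 x 50.
#' @param cellKm cell size in km (default 1, the working resolution).
#' @param smoothness correlation length of the background field, in cells.
#' @param noiseAmp amplitude of the background field relative to the bumps.
#' @param maxElevM approximate maximum elevation in metres.
#' @param refLon,refLat geographic origin of the grid.
#' @return An [Archipelago-class].
#' @export
makeArchipelago <- function(seed, nIslands = 5, gridShape = c(150, 150),
                            cellKm = 1, smoothness = 10, noiseAmp = 0.55,
                            maxElevM = 900, refLon = 25, refLat = 36.5) {
  stopifnot(gridShape[1] >= 50, gridShape[2] >= 50, nIslands >= 1)
  seed <- as.integer(seed)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  nr <- gridShape[1]; nc <- gridShape[2]
  field <- smoothField(nr, nc, smoothness)

  # island centres: rejection-sample for minimum separation
  minSep <- 1.25 * min(nr, nc) / (sqrt(nIslands) + 1)
  centers <- matrix(NA_real_, nIslands, 2)
  placed <- 0; tries <- 0
  while (placed < nIslands && tries < 5000) {
    tries <- tries + 1
    cand <- c(runif(1, 0.15 * nr, 0.85 * nr), runif(1, 0.15 * nc, 0.85 * nc))
    if (placed == 0 ||
        min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                 (centers[seq_len(placed), 2] - cand[2])^2)) >= minSep) {
      placed <- placed + 1
      centers[placed, ] <- cand
    }
  }
  centers <- centers[seq_len(placed), , drop = FALSE]

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # compose with the max so close islands do not fuse through land bridges
  bump <- matrix(0, nr, nc)
  radius <- runif(placed, 0.07, 0.12) * min(nr, nc)
  for (k in seq_len(placed)) {
    d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
    bump <- pmax(bump, exp(-d2 / (2 * radius[k]^2)))
  }

  score <- bump + noiseAmp * 0.2 * field - 0.45
  land <- score > 0
  # drop speck components (< 5 cells)
  comp <- maskComponents(land)
  if (all(is.na(comp))) stop("zero land cells after thresholding; adjust parameters")
  keep <- as.integer(names(which(table(comp) >= 5)))
  land <- !is.na(comp) & comp %in% keep
  if (!any(land)) stop("zero land cells after thresholding; adjust parameters")

  dem <- matrix(NA_real_, nr, nc)
  dem[land] <- score[land] / max(score[land]) * maxElevM
  dem[land][dem[land] <= 0] <- 0.5   # guard: land strictly above sea level

  demGrid <- rasterGrid(dem, cellKm = cellKm, refLon = refLon, refLat = refLat)
  maskGrid <- rasterGrid(ifelse(land, 1, 0), cellKm = cellKm, refLon = refLon,
                         refLat = refLat)

  # settlements: one random land cell per island, extras on the largest
  comp <- maskComponents(land)
  ids <- sort(unique(comp[!is.na(comp)]))
  cc <- cellCentersXY(demGrid)
  setxy <- NULL
  for (i in ids) {
    cells <- which(!is.na(comp) & comp == i)
    pick <- cells[sample.int(length(cells), 1)]
    setxy <- rbind(setxy, c(cc$x[pick], cc$y[pick]))
  }
  big <- which(!is.na(comp) & comp == ids[1])
  nExtra <- max(0, 4 - length(ids))
  if (length(big) > 10 && nExtra > 0) {
    pick <- big[sample.int(length(big), nExtra)]
    setxy <- rbind(setxy, cbind(cc$x[pick], cc$y[pick]))
  }
  colnames(setxy) <- c("x", "y")

  new("Archipelago", dem = demGrid, landMask = maskGrid,
      settlements = setxy, seed = seed)
}

#' Number of land components (islands) of an archipelago
#'
#' @param arch an [Archipelago-class].
#' @return integer count of 4-connected land components.
#' @export
countIslands <- function(arch) {
  comp <- maskComponents(!is.na(arch@dem@values) & arch@dem@values > 0)
  length(unique(comp[!is.na(comp)]))
}

#' Island (component) id raster
#'
#' @param arch an [Archipelago-class].
#' @return A [RasterGrid-class] of integer component ids (1 = largest island).
#' @export
islandIdGrid <- function(arch) {
  comp <- maskComponents(!is.na(arch@dem@values) & arch@dem@values > 0)
  sameGrid(arch@dem, comp + 0)
}

setMethod("show", "Archipelago", function(object) {
  land <- sum(!is.na(object@dem@values))
  cat(sprintf("Archipelago: %d land cells on a %d x %d grid (%d islands, seed %d)\n",
              land, nrow(object@dem@values), ncol(object@dem@values),
              countIslands(object), object@seed))
  invisible(object)
})

#' Generate baseline monthly climate for an archipelago
#'
#' Temperature is a latitudinal gradient plus a seasonal sinusoid (warmest in
#' July), cooled with elevation by a lapse rate, with spatially smooth
#' Gaussian noise per month. Precipitation follows a Mediterranean regime:
#' the wet-season share falls in the six winter months (Nov-Apr), with an
#' orographic enhancement and multiplicative lognormal noise.
#'
#' @param arch an [Archipelago-class].
#' @param lapseRate temperature lapse rate, degC per km of elevation.
#' @param seasonalAmp seasonal semi-amplitude of monthly mean temperature, degC.
#' @param wetSeasonShare fraction of annual precipitation in Nov-Apr.
#' @param seaLevelT annual-mean sea-level temperature at the grid origin, degC.
#' @param latGradient cooling per degree of latitude northwards, degC.
#' @param diurnalRange tmax - tmin, degC (constant).
#' @param annualPrecMm mean annual precipitation at sea level, mm.
#' @param orographicFactor fractional precipitation increase per km elevation.
#' @param noiseSd sd of the persistent (month-invariant) temperature anomaly
#'   field, degC (0 = off). Anomalies are persistent because they represent
#'   stationary orographic and coastal effects, not weather.
#' @param monthNoiseSd sd of the additional independent monthly temperature
#'   jitter fields, degC (0 = off).
#' @param precNoiseSd lognormal sigma of the persistent precipitation
#'   anomaly field (0 = off).
#' @param noiseRange correlation length of noise fields, cells.
#' @param seed integer seed.
#' @return A [ClimateSet-class] with scenario `"baseline"`.
#' @export
makeMonthlyClimate <- function(arch, lapseRate = 6.5, seasonalAmp = 7,
                               wetSeasonShare = 0.75, seaLevelT = 18,
                               latGradient = 0.8, diurnalRange = 8,
                               annualPrecMm = 600, orographicFactor = 0.25,
                               noiseSd = 0.6, monthNoiseSd = 0.15,
                               precNoiseSd = 0.35,
                               noiseRange = 8, seed = 1) {
  stopifnot(lapseRate >= 0, wetSeasonShare >= 0, wetSeasonShare <= 1)
  force(arch)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  dem <- arch@dem
  nr <- nrow(dem@values); nc <- ncol(dem@values)
  lat <- latitudeGrid(dem)@values
  elevKm <- dem@values / 1000
  land <- !is.na(dem@values)

  base <- seaLevelT - latGradient * (lat - dem@refLat) - lapseRate * elevKm
  tAnom <- if (noiseSd > 0) noiseSd * smoothField(nr, nc, noiseRange) else 0
  pAnom <- if (precNoiseSd > 0)
    exp(precNoiseSd * smoothField(nr, nc, noiseRange) - precNoiseSd^2 / 2)
  else 1
  winter <- c(11, 12, 1, 2, 3, 4)
  wWet <- wetSeasonShare / 6; wDry <- (1 - wetSeasonShare) / 6

  tmin <- tmax <- prec <- vector("list", 12)
  for (m in 1:12) {
    seas <- -cos(2 * pi * (m - 1) / 12)          # -1 in Jan, +1 in Jul
    tj <- if (monthNoiseSd > 0) monthNoiseSd * smoothField(nr, nc, noiseRange)
          else 0
    tmean <- base + seasonalAmp * seas + tAnom + tj
    tmn <- tmean - diurnalRange / 2
    tmx <- tmean + diurnalRange / 2
    w <- if (m %in% winter) wWet else wDry
    pm <- annualPrecMm * w * (1 + orographicFactor * elevKm) * pAnom
    tmn[!land] <- NA; tmx[!land] <- NA; pm[!land] <- NA
    tmin[[m]] <- sameGrid(dem, tmn)
    tmax[[m]] <- sameGrid(dem, tmx)
    prec[[m]] <- sameGrid(dem, pmax(pm, 0))
  }
  new("ClimateSet", tmin = tmin, tmax = tmax, prec = prec,
      scenario = "baseline")
}

#' Scenario specification
#'
#' A (GCM, RCP, time-slice) triple addressing one projected climate stack.
#'
#' @param gcm circulation-model label (e.g. `"ccsm4-like"`).
#' @param rcp emissions-pathway label (`"rcp45"` mild, `"rcp85"` severe).
#' @param slice time-slice label (`"2020s"`, `"2050s"`, `"2080s"`).
#' @return list of class `ScenarioSpec`.
#' @export
scenarioSpec <- function(gcm, rcp, slice) {
  structure(list(gcm = gcm, rcp = rcp, slice = slice), class = "ScenarioSpec")
}

#' @export
format.ScenarioSpec <- function(x, ...) paste(x$gcm, x$rcp, x$slice, sep = "|")

#' @export
print.ScenarioSpec <- function(x, ...) {
  cat("ScenarioSpec:", format(x), "\n"); invisible(x)
}

#' Warming and drying deltas implied by a scenario
#'
#' Fixed per (RCP, slice) warming/drying schedule, scaled by a per-GCM
#' sensitivity factor (the hot-model archetype warms ~15% more).
#'
#' @param spec a `ScenarioSpec`.
#' @return list with `deltaT` (degC) and `precFactor` (multiplier).
#' @export
scenarioDelta <- function(spec) {
  sl <- match.arg(spec$slice, c("2020s", "2050s", "2080s"))
  rcp <- match.arg(spec$rcp, c("rcp45", "rcp85"))
  dt <- switch(rcp,
    rcp45 = c(`2020s` = 0.8, `2050s` = 1.5, `2080s` = 2.2),
    rcp85 = c(`2020s` = 1.0, `2050s` = 2.5, `2080s` = 4.0))[[sl]]
  pf <- switch(rcp,
    rcp45 = c(`2020s` = 0.97, `2050s` = 0.94, `2080s` = 0.91),
    rcp85 = c(`2020s` = 0.95, `2050s` = 0.88, `2080s` = 0.80))[[sl]]
  gcmFactor <- switch(spec$gcm, `hadgem2-like` = 1.15, `ensemble-like` = 1.05, 1)
  list(deltaT = dt * gcmFactor, precFactor = 1 - (1 - pf) * gcmFactor)
}

#' Apply a warming/drying scenario to a climate set
#'
#' Shifts every monthly temperature by `deltaT` and multiplies every monthly
#' precipitation by `precFactor`; the scenario label is recorded.
#'
#' @param clim a [ClimateSet-class].
#' @param deltaT additive temperature change, degC.
#' @param precFactor multiplicative precipitation change (> 0).
#' @param spec optional `ScenarioSpec` recorded in the output.
#' @return A [ClimateSet-class].
#' @export
applyScenario <- function(clim, deltaT, precFactor, spec = NULL) {
  stopifnot(precFactor > 0)
  out <- clim
  for (m in 1:12) {
    out@tmin[[m]]@values <- clim@tmin[[m]]@values + deltaT
    out@tmax[[m]]@values <- clim@tmax[[m]]@values + deltaT
    out@prec[[m]]@values <- clim@prec[[m]]@values * precFactor
  }
  out@scenario <- if (is.null(spec)) sprintf("dT%+.2f|P%.2f", deltaT, precFactor)
                  else format(spec)
  out
}

# --- virtual species --------------------------------------------------------

#' Construct a virtual species
#'
#' @param name species identifier.
#' @param niche named list of `c(opt =, tol =)` Gaussian responses, keyed by
#'   predictor-layer name.
#' @param prevalence intended approximate suitable fraction of land
#'   (informational).
#' @param detectabilityDecay default per-km accessibility decay for sampling.
#' @param island island id restriction (`NA` = none).
#' @return A [VirtualSpecies-class].
#' @export
virtualSpecies <- function(name, niche, prevalence = NA_real_,
                           detectabilityDecay = 0, island = NA_integer_) {
  new("VirtualSpecies", name = name, niche = niche, prevalence = prevalence,
      detectabilityDecay = detectabilityDecay, island = as.integer(island))
}

setMethod("show", "VirtualSpecies", function(object) {
  cat(sprintf("VirtualSpecies '%s': niche on %s%s\n", object@name,
              paste(names(object@niche), collapse = " x "),
              if (is.na(object@island)) "" else sprintf(" (endemic to island %d)",
                                                        object@island)))
  invisible(object)
})

#' True suitability surface of a virtual species
#'
#' Product of Gaussian responses over the species' niche predictors,
#' rescaled to a maximum of 1 on land; zero outside the species' island for
#' endemics.
#'
#' @param vs a [VirtualSpecies-class].
#' @param env [LayerStack-class] containing every niche predictor.
#' @param arch the [Archipelago-class] (for island restriction).
#' @return A [RasterGrid-class] in `[0, 1]`, nodata on sea.
#' @export
trueSuitability <- function(vs, env, arch) {
  stopifnot(all(names(vs@niche) %in% layerNames(env)))
  template <- env@layers[[1]]
  s <- matrix(1, nrow(template@values), ncol(template@values))
  for (nm in names(vs@niche)) {
    p <- vs@niche[[nm]]
    x <- getLayer(env, nm)@values
    s <- s * exp(-(x - p[["opt"]])^2 / (2 * p[["tol"]]^2))
  }
  if (!is.na(vs@island)) {
    ids <- islandIdGrid(arch)@values
    s[is.na(ids) | ids != vs@island] <- 0
  }
  land <- !is.na(arch@dem@values)
  s[!land] <- NA
  mx <- max(s[land], na.rm = TRUE)
  if (mx > 0) s <- s / mx
  sameGrid(template, s)
}

#' Default virtual-species pool
#'
#' Twelve species spanning four archetypes defined on annual mean
#' temperature (`bio1`) and annual precipitation (`bio12`): cold-adapted
#' (optimum in the coolest decile of land climate, so warming contracts
#' them), warm-adapted (optimum in the warmest decile), generalists (broad
#' tolerances), and single-island endemics. One cold-adapted species
#' (`strong_niche`) has a deliberately narrow niche and serves as the
#' strong-signal recovery benchmark.
#'
#' @param env baseline predictor [LayerStack-class] containing `bio1` and
#'   `bio12` (used to place optima at climate quantiles).
#' @return named list of [VirtualSpecies-class] objects.
#' @export
defaultVirtualSpecies <- function(env) {
  b1 <- getLayer(env, "bio1")@values; b1 <- b1[!is.na(b1)]
  b12 <- getLayer(env, "bio12")@values; b12 <- b12[!is.na(b12)]
  q1 <- quantile(b1, c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  q12 <- quantile(b12, c(0.25, 0.5, 0.75), names = FALSE)
  r1 <- diff(range(b1)); r12 <- diff(range(b12))
  n <- function(o1, t1, o12, t12)
    list(bio1 = c(opt = o1, tol = t1), bio12 = c(opt = o12, tol = t12))
  sp <- list(
    virtualSpecies("strong_niche", n(q1[2], 0.10 * r1, q12[3], 0.5 * r12),
                   prevalence = 0.1, detectabilityDecay = 0.02),
    virtualSpecies("cold_montane", n(q1[1], 0.12 * r1, q12[3], 0.6 * r12),
                   prevalence = 0.1, detectabilityDecay = 0.02),
    virtualSpecies("cold_mesic", n(q1[3], 0.15 * r1, q12[2], 0.6 * r12),
                   prevalence = 0.15, detectabilityDecay = 0.02),
    virtualSpecies("warm_coastal", n(q1[6], 0.15 * r1, q12[1], 0.6 * r12),
                   prevalence = 0.15, detectabilityDecay = 0.02),
    virtualSpecies("warm_arid", n(q1[6], 0.12 * r1, q12[1], 0.4 * r12),
                   prevalence = 0.1, detectabilityDecay = 0.03),
    virtualSpecies("warm_thermophile", n(q1[5], 0.18 * r1, q12[1], 0.8 * r12),
                   prevalence = 0.2, detectabilityDecay = 0.02),
    virtualSpecies("generalist_wide", n(q1[4], 0.45 * r1, q12[2], 1.2 * r12),
                   prevalence = 0.6, detectabilityDecay = 0.01),
    virtualSpecies("generalist_mid", n(q1[4], 0.30 * r1, q12[2], 0.9 * r12),
                   prevalence = 0.4, detectabilityDecay = 0.01),
    virtualSpecies("generalist_moist", n(q1[3], 0.35 * r1, q12[3], 1.0 * r12),
                   prevalence = 0.5, detectabilityDecay = 0.01),
    virtualSpecies("endemic_one", n(q1[4], 0.25 * r1, q12[2], 0.9 * r12),
                   prevalence = 0.05, detectabilityDecay = 0.02, island = 1L),
    virtualSpecies("endemic_two", n(q1[3], 0.20 * r1, q12[2], 0.8 * r12),
                   prevalence = 0.05, detectabilityDecay = 0.02, island = 2L),
    virtualSpecies("endemic_cold", n(q1[2], 0.15 * r1, q12[3], 0.8 * r12),
                   prevalence = 0.04, detectabilityDecay = 0.02, island = 1L))
  setNames(sp, vapply(sp, function(v) v@name, ""))
}

#' Sample biased occurrence records for a virtual species
#'
#' Records are drawn from land cells with probability proportional to
#' `true suitability x exp(-biasStrength x distance to nearest settlement)`,
#' emulating accessibility-driven sampling bias.
#'
#' @param vs a [VirtualSpecies-class].
#' @param env predictor [LayerStack-class] holding the niche layers.
#' @param arch the [Archipelago-class].
#' @param nRecords number of records to draw (with replacement over cells).
#' @param biasStrength per-km decay of sampling effort with distance to the
#'   nearest settlement (default: the species' `detectabilityDecay`).
#' @param seed integer seed.
#' @return list with `occurrences` (data.frame `species`, `lon`, `lat`,
#'   `stage = "raw"`) and `suitability` (the true suitability raster).
#' @export
sampleVirtualOccurrences <- function(vs, env, arch, nRecords,
                                     biasStrength = NULL, seed = 1) {
  stopifnot(nRecords >= 1)
  if (is.null(biasStrength)) biasStrength <- vs@detectabilityDecay
  force(env); force(arch)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  suit <- trueSuitability(vs, env, arch)
  dset <- distanceToPoints(arch@dem, arch@settlements)
  cells <- validCells(suit)
  w <- suit@values[cells] * exp(-biasStrength * dset@values[cells])
  if (all(w <= 0 | !is.finite(w)))
    stop("all sampling weights are zero; species has no suitable accessible cells")
  pick <- sample(cells, nRecords, replace = TRUE, prob = w)
  ll <- lonLatFromCell(suit, pick)
  list(occurrences = data.frame(species = vs@name, lon = ll$lon, lat = ll$lat,
                                stage = "raw", stringsAsFactors = FALSE),
       suitability = suit)
}

# --- protected areas & human modification ----------------------------------

#' Generate synthetic protected-area polygons
#'
#' Random rectangular land patches are accumulated until their rasterized
#' union covers the requested fraction of land cells (within +-0.05); the
#' final patch is shrunk when it overshoots. Coverage is measured with the
#' cell-centre rule on land cells; sea is always outside.
#'
#' @param arch an [Archipelago-class].
#' @param coverage target fraction of land cells covered, in `[0, 1]`.
#' @param seed integer seed.
#' @return list of polygons (each a closed ring matrix with columns `x`, `y`
#'   in km), class `"paSet"`, with the source grid attached as an attribute.
#' @export
makeProtectedAreas <- function(arch, coverage, seed = 1) {
  stopifnot(coverage >= 0, coverage <= 1)
  force(arch)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  grid <- arch@dem
  polys <- list()
  if (coverage == 0)
    return(structure(polys, class = "paSet", grid = grid))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  if (coverage >= 1) {
    x0 <- grid@xllKm - grid@cellKm; x1 <- grid@xllKm + (nc + 1) * grid@cellKm
    y0 <- grid@yllKm - grid@cellKm; y1 <- grid@yllKm + (nr + 1) * grid@cellKm
    ring <- cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
    return(structure(list(ring), class = "paSet", grid = grid))
  }
  land <- validCells(grid)
  nLand <- length(land)
  target <- coverage * nLand
  cc <- cellCentersXY(grid)
  covered <- rep(FALSE, nLand)
  cellX <- cc$x[land]; cellY <- cc$y[land]
  mkRect <- function(cx, cy, a, b)
    cbind(x = c(cx - a, cx + a, cx + a, cx - a, cx - a),
          y = c(cy - b, cy - b, cy + b, cy + b, cy - b))
  inRect <- function(cx, cy, a, b)
    abs(cellX - cx) <= a & abs(cellY - cy) <= b
  guard <- 0
  while (sum(covered) < target - 0.02 * nLand && guard < 500) {
    guard <- guard + 1
    seedCell <- sample.int(nLand, 1)
    cx <- cellX[seedCell]; cy <- cellY[seedCell]
    a <- runif(1, 2, 9) * grid@cellKm
    b <- runif(1, 2, 9) * grid@cellKm
    newCov <- covered | inRect(cx, cy, a, b)
    if (sum(newCov) > target + 0.04 * nLand) {
      # shrink until within band
      for (f in seq(0.9, 0.1, by = -0.1)) {
        newCov <- covered | inRect(cx, cy, a * f, b * f)
        if (sum(newCov) <= target + 0.04 * nLand) { a <- a * f; b <- b * f; break }
      }
      if (sum(newCov) > target + 0.04 * nLand) next
    }
    covered <- newCov
    polys[[length(polys) + 1]] <- mkRect(cx, cy, a, b)
  }
  structure(polys, class = "paSet", grid = grid)
}

#' Generate a synthetic human-modification raster
#'
#' A smooth random field blended with settlement-proximity pressure, scaled
#' to `[0, 1]`; nodata on sea. Emulates a cumulative human-impact index.
#'
#' @param arch an [Archipelago-class].
#' @param seed integer seed.
#' @param pressureRangeKm e-folding distance of settlement pressure, km.
#' @return A [RasterGrid-class] in `[0, 1]`.
#' @export
makeHumanModification <- function(arch, seed = 1, pressureRangeKm = 6) {
  force(arch)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  grid <- arch@dem
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  f <- smoothField(nr, nc, 10)
  d <- distanceToPoints(grid, arch@settlements)@values
  g <- 0.55 * exp(-d / pressureRangeKm) + 0.30 * pnorm(f) + 0.10
  g <- pmin(pmax(g, 0), 1)
  g[is.na(grid@values)] <- NA
  sameGrid(grid, g)
}

# --- occurrence / polygon IO ------------------------------------------------

#' Write occurrence records to CSV
#'
#' @param occ data.frame with `species`, `lon`, `lat` (and optional `stage`).
#' @param file output path.
#' @export
writeOccurrences <- function(occ, file) {
  write.csv(occ[, intersect(c("species", "lon", "lat", "stage"), names(occ))],
            file, row.names = FALSE)
  invisible(file)
}

#' Read occurrence records from CSV
#'
#' @param file path to a CSV with columns `species`, `lon`, `lat`.
#' @return data.frame with a `stage` column (default `"raw"`).
#' @export
readOccurrences <- function(file) {
  occ <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  if (is.null(occ$stage)) occ$stage <- "raw"
  occ
}

#' Write protected-area polygons as GeoJSON
#'
#' Planar km rings are converted to lon/lat through the source grid's origin.
#'
#' @param pa a `paSet` (see [makeProtectedAreas()]).
#' @param file output path.
#' @export
writeGeoJSON <- function(pa, file) {
  grid <- attr(pa, "grid")
  feats <- lapply(seq_along(pa), function(i) {
    ll <- xyToLonLat(grid, pa[[i]][, "x"], pa[[i]][, "y"])
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "Polygon",
                         coordinates = list(mapply(function(a, b) c(a, b),
                                                   ll$lon, ll$lat,
                                                   SIMPLIFY = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Read protected-area polygons from GeoJSON
#'
#' @param file GeoJSON path (Polygon features, first ring used).
#' @param grid reference [RasterGrid-class] for the km mapping.
#' @return a `paSet`.
#' @export
readGeoJSON <- function(file, grid) {
  js <- jsonlite::read_json(file)
  polys <- lapply(js$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    lon <- vapply(ring, function(p) as.numeric(p[[1]]), 1)
    lat <- vapply(ring, function(p) as.numeric(p[[2]]), 1)
    xy <- lonLatToXY(grid, lon, lat)
    cbind(x = xy$x, y = xy$y)
  })
  structure(polys, class = "paSet", grid = grid)
}
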