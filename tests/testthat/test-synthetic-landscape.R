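test_that("archipelago generation is deterministic and masks land correctly", {
  a1 <- makeArchipelago(1, nIslands = 4, gridShape = c(100, 100))
  a2 <- makeArchipelago(1, nIslands = 4, gridShape = c(100, 100))
  expect_identical(gridValues(a1@dem), gridValues(a2@dem))
  expect_identical(a1@settlements, a2@settlements)
  land <- !is.na(gridValues(a1@dem)) & gridValues(a1@dem) > 0
  expect_identical(unname(gridValues(a1@landMask) > 0), unname(land))
  n <- countIslands(a1)
  expect_gte(n, 2)
  expect_lte(n, 6)
})

test_that("one island with heavy smoothing gives a single component", {
  a <- makeArchipelago(5, nIslands = 1, gridShape = c(60, 60),
                       smoothness = 20, noiseAmp = 0.2)
  expect_equal(countIslands(a), 1)
})

test_that("monthly temperature follows the lapse rate and seasonal amplitude", {
  arch <- fixArch()
  clim <- makeMonthlyClimate(arch, lapseRate = 6.5, noiseSd = 0,
                             monthNoiseSd = 0, precNoiseSd = 0, seed = 1)
  tavg <- Reduce(`+`, lapply(1:12, function(m)
    (gridValues(clim@tmin[[m]]) + gridValues(clim@tmax[[m]])) / 2)) / 12
  dem <- gridValues(arch@dem)
  lat <- gridValues(latitudeGrid(arch@dem))
  cells <- which(!is.na(dem))
  # pick two same-latitude-row cells with a large elevation difference
  rows <- (cells - 1) %% nrow(dem) + 1
  byRow <- split(cells, rows)
  byRow <- byRow[vapply(byRow, length, 1L) >= 2]
  found <- FALSE
  for (cs in byRow) {
    dd <- dem[cs]
    i <- which.max(dd); j <- which.min(dd)
    if (dd[i] - dd[j] > 400) {
      expected <- 6.5 * (dd[i] - dd[j]) / 1000
      expect_equal(tavg[cs[j]] - tavg[cs[i]], expected, tolerance = 1e-6)
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # zero seasonal amplitude (noise off) makes all months identical
  flat <- makeMonthlyClimate(arch, seasonalAmp = 0, noiseSd = 0,
                             monthNoiseSd = 0, precNoiseSd = 0, seed = 1)
  t1 <- gridValues(flat@tmin[[1]])
  for (m in 2:12)
    expect_equal(gridValues(flat@tmin[[m]]), t1, tolerance = 1e-12)

  # full wet-season share leaves the six summer months dry
  wet <- makeMonthlyClimate(arch, wetSeasonShare = 1, seed = 1)
  for (m in 5:10)
    expect_equal(max(gridValues(wet@prec[[m]]), na.rm = TRUE), 0)
})

test_that("scenario application shifts temperatures and scales precipitation", {
  clim <- fixClim()
  same <- applyScenario(clim, 0, 1)
  expect_equal(gridValues(same@tmax[[7]]), gridValues(clim@tmax[[7]]))
  expect_equal(gridValues(same@prec[[1]]), gridValues(clim@prec[[1]]))

  warm <- applyScenario(clim, 3, 0.8, scenarioSpec("ccsm4-like", "rcp85", "2080s"))
  b0 <- deriveBioclim(clim); b1 <- deriveBioclim(warm)
  expect_equal(gridValues(getLayer(b1, "bio1")),
               gridValues(getLayer(b0, "bio1")) + 3, tolerance = 1e-9)
  expect_equal(gridValues(getLayer(b1, "bio12")),
               gridValues(getLayer(b0, "bio12")) * 0.8, tolerance = 1e-9)
  expect_equal(warm@scenario, "ccsm4-like|rcp85|2080s")
})

test_that("uniform-suitability unbiased sampling is proportional to island area", {
  arch <- fixArch()
  bio <- fixBio()
  flat <- virtualSpecies("flat", list(bio1 = c(opt = 0, tol = 1e6)))
  samp <- sampleVirtualOccurrences(flat, bio, arch, 5000, biasStrength = 0,
                                   seed = 21)
  ids <- islandIdGrid(arch)
  cellIdx <- cellFromLonLat(arch@dem, samp$occurrences$lon,
                            samp$occurrences$lat)$cell
  isl <- gridValues(ids)[cellIdx]
  sizes <- table(gridValues(ids)[validCells(arch@dem)])
  obs <- table(factor(isl, levels = names(sizes)))
  p <- as.numeric(sizes) / sum(sizes)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p))
  expect_gt(chi$p.value, 1e-3)
})

test_that("extreme accessibility bias pins records to settlements and endemics stay home", {
  arch <- fixArch()
  bio <- fixBio()
  flat <- virtualSpecies("flat", list(bio1 = c(opt = 0, tol = 1e6)))
  samp <- sampleVirtualOccurrences(flat, bio, arch, 300, biasStrength = 50,
                                   seed = 3)
  xy <- lonLatToXY(arch@dem, samp$occurrences$lon, samp$occurrences$lat)
  dmin <- vapply(seq_len(nrow(xy)), function(i)
    sqrt(min((arch@settlements[, 1] - xy$x[i])^2 +
             (arch@settlements[, 2] - xy$y[i])^2)), 1)
  expect_lte(max(dmin), sqrt(2) * cellKm(arch@dem) + 1e-9)

  end <- virtualSpecies("end", list(bio1 = c(opt = 0, tol = 1e6)), island = 2L)
  sampE <- sampleVirtualOccurrences(end, bio, arch, 200, seed = 4)
  cellsE <- cellFromLonLat(arch@dem, sampE$occurrences$lon,
                           sampE$occurrences$lat)$cell
  expect_true(all(gridValues(islandIdGrid(arch))[cellsE] == 2))

  zero <- virtualSpecies("zero", list(bio1 = c(opt = 1e5, tol = 1e-3)))
  suit <- trueSuitability(zero, bio, arch)
  expect_true(all(gridValues(suit)[validCells(suit)] < 1e-6 |
                  gridValues(suit)[validCells(suit)] == 1))
})

test_that("protected-area coverage hits its target band", {
  arch <- fixArch()
  land <- validCells(arch@dem)
  expect_length(makeProtectedAreas(arch, 0, seed = 1), 0)

  full <- makeProtectedAreas(arch, 1, seed = 1)
  mFull <- rasterizePa(full, arch@dem)
  expect_true(all(gridValues(mFull)[land] > 0))

  pa <- makeProtectedAreas(arch, 0.28, seed = 2)
  m <- rasterizePa(pa, arch@dem)
  cov <- mean(gridValues(m)[land] > 0)
  expect_gte(cov, 0.23)
  expect_lte(cov, 0.33)
})

test_that("human-modification surface is bounded, settlement-elevated and deterministic", {
  arch <- fixArch()
  g1 <- makeHumanModification(arch, seed = 9)
  g2 <- makeHumanModification(arch, seed = 9)
  expect_identical(gridValues(g1), gridValues(g2))
  v <- gridValues(g1)[validCells(g1)]
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  sCells <- cellFromLonLat(arch@dem,
                           xyToLonLat(arch@dem, arch@settlements[, 1],
                                      arch@settlements[, 2])$lon,
                           xyToLonLat(arch@dem, arch@settlements[, 1],
                                      arch@settlements[, 2])$lat)$cell
  expect_gt(min(gridValues(g1)[sCells]), median(v))
})

test_that("niche position is recoverable from biased samples (sanity oracle)", {
  arch <- fixArch()
  bio <- fixBio()
  b1 <- gridValues(getLayer(bio, "bio1"))
  landMean <- mean(b1[validCells(arch@dem)])
  sp <- defaultVirtualSpecies(bio)
  sampCold <- sampleVirtualOccurrences(sp$cold_montane, bio, arch, 500, seed = 5)
  sampWarm <- sampleVirtualOccurrences(sp$warm_coastal, bio, arch, 500, seed = 6)
  coldAt <- b1[cellFromLonLat(arch@dem, sampCold$occurrences$lon,
                              sampCold$occurrences$lat)$cell]
  warmAt <- b1[cellFromLonLat(arch@dem, sampWarm$occurrences$lon,
                              sampWarm$occurrences$lat)$cell]
  expect_lt(mean(coldAt), landMean)
  expect_gt(mean(warmAt), landMean)
})

test_that("occurrence and polygon files round-trip", {
  occ <- data.frame(species = c("a", "b"), lon = c(25.1, 25.3),
                    lat = c(36.8, 36.9), stage = "raw")
  f <- file.path(tempdir(), "occ.csv")
  writeOccurrences(occ, f)
  expect_equal(readOccurrences(f)$species, c("a", "b"))

  arch <- fixArch()
  pa <- makeProtectedAreas(arch, 0.2, seed = 3)
  gj <- file.path(tempdir(), "pa.geojson")
  writeGeoJSON(pa, gj)
  pa2 <- readGeoJSON(gj, arch@dem)
  expect_equal(length(pa2), length(pa))
  m1 <- rasterizePa(pa, arch@dem); m2 <- rasterizePa(pa2, arch@dem)
  expect_equal(gridValues(m1), gridValues(m2))
})
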