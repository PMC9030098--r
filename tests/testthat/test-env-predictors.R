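test_that("bioclim variables match the hand-computed toy series", {
  # tmin 2..13, tmax 10..21, prec 10..120 by month; oracle computed with an
  # explicit-loop implementation of the wrap-around quarter definitions
  clim <- toyClimate(as.list(2:13), as.list(10:21), as.list(10 * (1:12)))
  bio <- deriveBioclim(clim)
  expected <- c(11.5, 8, 42.10526316, 360.55512755, 21, 2, 19, 16, 7, 16, 7,
                780, 120, 10, 54.62956478, 330, 60, 330, 60)
  got <- vapply(paste0("bio", 1:19), function(nm)
    gridValues(getLayer(bio, nm))[1, 1], 1)
  expect_equal(unname(got), expected, tolerance = 1e-7)
})

test_that("degenerate climates give the expected bioclim constants", {
  clim <- toyClimate(rep(list(8), 12), rep(list(12), 12), rep(list(100), 12))
  bio <- deriveBioclim(clim)
  at <- function(nm) gridValues(getLayer(bio, nm))[1, 1]
  expect_equal(at("bio1"), 10)
  expect_equal(at("bio4"), 0)
  expect_equal(at("bio7"), at("bio5") - at("bio6"))
  expect_equal(at("bio12"), 1200)
  expect_equal(at("bio13"), 100)
  expect_equal(at("bio14"), 100)
  expect_equal(at("bio15"), 0)
  expect_error(new("ClimateSet", tmin = rep(list(rasterGrid(matrix(1), dim = c(1, 1))), 11),
                   tmax = list(), prec = list()), "12 monthly")
})

test_that("vectorized quarter selection matches per-cell brute force", {
  clim <- randomClimate(77, nr = 10, nc = 10)
  bio <- deriveBioclim(clim)
  tmin <- sapply(clim@tmin, function(g) as.vector(gridValues(g)))
  tmax <- sapply(clim@tmax, function(g) as.vector(gridValues(g)))
  prec <- sapply(clim@prec, function(g) as.vector(gridValues(g)))
  tavg <- (tmin + tmax) / 2
  qs <- function(v, m) sum(v[((m - 1):(m + 1)) %% 12 + 1])
  for (cell in sample(100, 40)) {
    tq <- vapply(1:12, function(m) qs(tavg[cell, ], m), 1)
    pq <- vapply(1:12, function(m) qs(prec[cell, ], m), 1)
    pickLow <- function(v, by, mx) {
      idx <- if (mx) which(by == max(by)) else which(by == min(by))
      v[min(idx)]
    }
    expect_equal(gridValues(getLayer(bio, "bio10"))[cell],
                 pickLow(tq, tq, TRUE) / 3, tolerance = 1e-9)
    expect_equal(gridValues(getLayer(bio, "bio11"))[cell],
                 pickLow(tq, tq, FALSE) / 3, tolerance = 1e-9)
    expect_equal(gridValues(getLayer(bio, "bio8"))[cell],
                 pickLow(tq, pq, TRUE) / 3, tolerance = 1e-9)
    expect_equal(gridValues(getLayer(bio, "bio16"))[cell],
                 pickLow(pq, pq, TRUE), tolerance = 1e-9)
    expect_equal(gridValues(getLayer(bio, "bio19"))[cell],
                 pickLow(pq, tq, FALSE), tolerance = 1e-9)
  }
})

test_that("PET increases with temperature and respects quarter ordering", {
  # two cells identical except temperature
  mkT <- function(base) lapply(1:12, function(m) base + m)
  clim <- toyClimate(mkT(5), mkT(13), rep(list(50), 12), nr = 1, nc = 2)
  for (m in 1:12) {
    v <- gridValues(clim@tmin[[m]]); v[1, 2] <- v[1, 2] - 8
    gridValues(clim@tmin[[m]]) <- v
    v <- gridValues(clim@tmax[[m]]); v[1, 2] <- v[1, 2] - 8
    gridValues(clim@tmax[[m]]) <- v
  }
  env <- deriveEnvirem(clim)
  pet <- gridValues(getLayer(env, "annualPET"))
  expect_gt(pet[1, 1], pet[1, 2])

  envArch <- deriveEnvirem(fixClim())
  cold <- gridValues(getLayer(envArch, "PETColdestQuarter"))
  warm <- gridValues(getLayer(envArch, "PETWarmestQuarter"))
  ok <- !is.na(cold)
  expect_true(all(cold[ok] <= warm[ok] + 1e-9))

  # a rain-free year maximizes the aridity index for the temperature regime
  dry <- toyClimate(mkT(5), mkT(13), rep(list(0), 12))
  expect_equal(gridValues(getLayer(deriveEnvirem(dry),
                                   "aridityIndexThornthwaite"))[1, 1], 100)
  badLat <- latitudeGrid(fixClim()@tmin[[1]])
  gridValues(badLat) <- gridValues(badLat) + 100
  expect_error(deriveEnvirem(fixClim(), latitude = badLat), "latitude")
})

test_that("topographic derivatives are exact on constructed surfaces", {
  flat <- rasterGrid(matrix(100, 12, 12), cellKm = 1)
  topo <- deriveTopographic(flat)
  inner <- gridValues(getLayer(topo, "slope"))[3:10, 3:10]
  expect_equal(max(abs(inner)), 0)
  expect_equal(max(abs(gridValues(getLayer(topo, "tpi"))[3:10, 3:10])), 0)
  expect_equal(max(abs(gridValues(getLayer(topo, "tri"))[3:10, 3:10])), 0)

  peak <- rasterGrid(matrix(0, 9, 9), cellKm = 1)
  v <- gridValues(peak); v[5, 5] <- 100; gridValues(peak) <- v
  t2 <- deriveTopographic(peak)
  expect_equal(gridValues(getLayer(t2, "tpi"))[5, 5], 100)
  expect_equal(gridValues(getLayer(t2, "tri"))[5, 5], 100)

  # inclined plane facing exactly south-west at 20 degrees
  nr <- 21; nc <- 21; cs <- 1000
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(nr - seq_len(nr), nr, nc)          # northing
  g <- tan(20 * pi / 180) / sqrt(2)
  plane <- rasterGrid((xs + ys) * cs / 1000 * g * 1000, cellKm = 1,
                      refLat = 39.5)
  t3 <- deriveTopographic(plane)
  expect_equal(gridValues(getLayer(t3, "slope"))[10, 10], 20, tolerance = 1e-6)
  expect_equal(gridValues(getLayer(t3, "aspect"))[10, 10], 225, tolerance = 1e-6)
  lat <- gridValues(latitudeGrid(plane))[10, 10] * pi / 180
  s <- 20 * pi / 180; folded <- pi                # |180 - |225 - 225|| = 180
  hliExp <- exp(-1.467 + 1.582 * cos(lat) * cos(s) -
                1.500 * cos(folded) * sin(s) * cos(lat) -
                0.262 * sin(lat) * sin(s) + 0.607 * sin(folded) * sin(s))
  expect_equal(gridValues(getLayer(t3, "hli"))[10, 10], hliExp,
               tolerance = 1e-9)
  expect_error(deriveTopographic(rasterGrid(matrix(NA_real_, 5, 5),
                                            cellKm = 1)), "no valid cells")
})

test_that("collinearity filter drops duplicates, noise survives, sums trip the VIF", {
  set.seed(42)
  mk <- function(v) rasterGrid(matrix(v, 50, 100), cellKm = 1)
  n <- 5000
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n); d <- rnorm(n)

  dup <- layerStack(list(a = mk(a), acopy = mk(a), b = mk(b)))
  repDup <- filterCollinear(dup, samples = 4000, seed = 1)
  expect_length(repDup$retained, 2)
  expect_equal(nrow(repDup$dropped), 1)
  expect_gte(repDup$dropped$value[1], 0.999)
  expect_true(grepl("rho", repDup$dropped$reason[1]))

  indep <- layerStack(list(a = mk(a), b = mk(b), c = mk(c), d = mk(d)))
  repInd <- filterCollinear(indep, samples = 5000, seed = 2)
  expect_length(repInd$retained, 4)

  # a sum of four weak components passes the rho screen but not the VIF
  s <- a + b + c + d
  vif <- layerStack(list(a = mk(a), b = mk(b), c = mk(c), d = mk(d),
                         s = mk(s)))
  repVif <- filterCollinear(vif, samples = 5000, seed = 3)
  expect_false("s" %in% repVif$retained ||
               !any(repVif$dropped$reason == "VIF"))
  dropped <- repVif$dropped
  expect_true(any(dropped$reason == "VIF" & dropped$value > 10))

  # zero-variance layers are removed with their own reason
  zv <- layerStack(list(a = mk(a), z = mk(rep(1, n))))
  repZ <- filterCollinear(zv, samples = 3000, seed = 4)
  expect_true(any(repZ$dropped$reason == "zero variance"))
})

test_that("retained set satisfies its own thresholds (self-verifying report)", {
  rep <- filterCollinear(fixFull(), samples = 3000,
                         keep = c("bio1", "bio12"), seed = 13)
  expect_setequal(c(rep$retained, rep$dropped$layer), layerNames(fixFull()))
  st <- subsetStack(fixFull(), rep$retained)
  X <- stackValues(st)
  set.seed(13)
  if (nrow(X) > 3000) X <- X[sample(nrow(X), 3000), ]
  rho <- abs(cor(X, method = "spearman"))
  diag(rho) <- 0
  expect_lt(max(rho), rep$rhoMax + 0.05)   # sampling jitter allowance
  for (nm in colnames(X)) {
    fit <- lm(X[, nm] ~ X[, setdiff(colnames(X), nm)])
    r2 <- summary(fit)$r.squared
    expect_lt(1 / (1 - r2), rep$vifMax * 1.2)
  }
})

test_that("uniform warming shifts additive bioclim layers and fixes the others", {
  clim <- fixClim()
  warm <- applyScenario(clim, 2.5, 1)
  b0 <- deriveBioclim(clim); b1 <- deriveBioclim(warm)
  for (nm in c("bio1", "bio5", "bio6", "bio8", "bio9", "bio10", "bio11"))
    expect_equal(gridValues(getLayer(b1, nm)),
                 gridValues(getLayer(b0, nm)) + 2.5, tolerance = 1e-9)
  for (nm in c("bio2", "bio4", "bio15"))
    expect_equal(gridValues(getLayer(b1, nm)),
                 gridValues(getLayer(b0, nm)), tolerance = 1e-9)
})

test_that("stack IO round-trips layers and provenance", {
  st <- subsetStack(fixBio(), c("bio1", "bio12"))
  d <- file.path(tempdir(), "stackio")
  writeStack(st, d)
  st2 <- readStack(d)
  expect_equal(layerNames(st2), c("bio1", "bio12"))
  expect_equal(gridValues(getLayer(st2, "bio1")),
               gridValues(getLayer(st, "bio1")), tolerance = 1e-6)
})
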