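test_that("pseudo-absences respect the minimum distance (brute force)", {
  arch <- fixArch()
  bio <- fixBio()
  sp <- defaultVirtualSpecies(bio)
  samp <- sampleVirtualOccurrences(sp$strong_niche, bio, arch, 150, seed = 41)
  occ <- dedupeOccurrences(samp$occurrences, arch@dem)
  pas <- generatePseudoAbsences("strong_niche", occ, arch@dem, minDist = 5.5,
                                nSets = 2, nPerSet = 200, seed = 1)
  pres <- occ[occ$species == "strong_niche", ]
  for (pa in pas) {
    for (i in seq_len(nrow(pres))) {
      d <- geosphere::distHaversine(cbind(pa$lon, pa$lat),
                                    c(pres$lon[i], pres$lat[i]),
                                    r = 6371008.8) / 1000
      expect_true(all(d >= 5.5))
    }
  }
  # minDist 0 excludes exactly the presence cells
  pa0 <- generatePseudoAbsences("strong_niche", occ, arch@dem, minDist = 0,
                                nSets = 1, nPerSet = 300, seed = 2)[[1]]
  presCells <- cellFromLonLat(arch@dem, pres$lon, pres$lat)$cell
  expect_length(intersect(pa0$cell, presCells), 0)
  # an island entirely within minDist of a presence contributes nothing
  ids <- gridValues(islandIdGrid(arch))
  expect_error(generatePseudoAbsences("strong_niche", occ, arch@dem,
                                      minDist = 500, nSets = 1,
                                      nPerSet = 10, seed = 3),
               "eligible")
})

test_that("variogram ranges behave for white noise and known correlation lengths", {
  arch <- fixArch()
  cells <- validCells(arch@dem)
  wn <- arch@dem
  set.seed(1)
  v <- gridValues(wn); v[cells] <- rnorm(length(cells)); gridValues(wn) <- v
  suppressWarnings(
    rWn <- medianAutocorrelationRange(layerStack(list(wn = wn)), seed = 2))
  expect_lte(as.numeric(rWn), 2 * cellKm(arch@dem))

  # Gaussian-kernel smoothing with sd 6 cells gives correlation
  # exp(-d^2 / (4 * 6^2)), i.e. an e-folding correlation length L = 12 km
  sm <- arch@dem
  set.seed(3)
  f <- islesdm:::smoothField(80, 80, 6)
  vv <- ifelse(is.na(gridValues(arch@dem)), NA, f)
  gridValues(sm) <- vv
  rSm <- medianAutocorrelationRange(layerStack(list(sm = sm)), seed = 2)
  expect_gte(as.numeric(rSm), 0.5 * 12)
  expect_lte(as.numeric(rSm), 3 * 12)

  both <- medianAutocorrelationRange(layerStack(list(a = wn, b = sm, c = wn)),
                                     seed = 2)
  per <- attr(both, "perLayer")
  expect_equal(as.numeric(both), median(per))
  flat <- arch@dem
  gridValues(flat) <- ifelse(is.na(gridValues(arch@dem)), NA, 1)
  expect_warning(medianAutocorrelationRange(layerStack(list(f = flat, s = sm)),
                                            seed = 2), "flat")
})

test_that("block CV keeps blocks intact, balances folds, and is seeded", {
  # 25 point-clusters on a 10-km lattice: one block each, equal counts
  centers <- expand.grid(x = seq(5, 45, by = 10), y = seq(5, 45, by = 10))
  pts <- data.frame(x = rep(centers$x, each = 4), y = rep(centers$y, each = 4),
                    label = rep(c(1, 1, 0, 0), 25))
  cv <- assignBlocks(pts, blockSize = 10, nFolds = 5, seed = 3)
  expect_equal(as.integer(table(cv$foldOfBlock)), rep(5L, 5))
  # same block -> same fold, exhaustively
  expect_true(all(tapply(cv$fold, cv$block, function(f) length(unique(f))) == 1))
  cv2 <- assignBlocks(pts, blockSize = 10, nFolds = 5, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  # leakage check: test and train never share a block
  for (f in 1:5) {
    testBlocks <- unique(cv$block[cv$fold == f])
    trainBlocks <- unique(cv$block[cv$fold != f])
    expect_length(intersect(testBlocks, trainBlocks), 0)
  }
  onePres <- data.frame(x = c(1, 1, 30), y = c(1, 1, 30), label = c(1, 1, 0))
  expect_error(assignBlocks(onePres, blockSize = 100, nFolds = 2, seed = 1),
               "degenerate|single block")
})

test_that("TSS follows its confusion-matrix definition", {
  expect_equal(tss(8, 3, 2, 7), 0.5)
  expect_equal(tss(10, 0, 0, 10), 1)
  expect_equal(tss(10, 10, 0, 0), 0)     # everything predicted present
  expect_error(tss(0, 5, 0, 5), "empty")
})

test_that("maxSSS threshold matches exhaustive search and the separable case", {
  expect_equal(maxSssThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  expect_error(maxSssThreshold(rep(0.4, 6), c(0, 0, 0, 1, 1, 1)), "identical")

  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    pred <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(pred)) < 2 || !any(labels == 1) || !any(labels == 0)) next
    thr <- maxSssThreshold(pred, labels)
    cand <- sort(unique(c(pred - 1e-9, pred + 1e-9)))
    sums <- vapply(cand, function(t) {
      p <- pred >= t
      sum(p & labels == 1) / sum(labels == 1) +
        sum(!p & labels == 0) / sum(labels == 0)
    }, 1)
    got <- sum(pred >= thr & labels == 1) / sum(labels == 1) +
      sum(pred < thr & labels == 0) / sum(labels == 0)
    expect_equal(got, max(sums), tolerance = 1e-9)
  }
})

test_that("label/score mirroring mirrors the threshold", {
  set.seed(7)
  for (i in 1:20) {
    n <- 40
    pred <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (!any(labels == 1) || !any(labels == 0)) next
    s <- sort(unique(pred))
    cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
    sums <- vapply(cand, function(t) {
      p <- pred >= t
      sum(p & labels == 1) / sum(labels == 1) +
        sum(!p & labels == 0) / sum(labels == 0)
    }, 1)
    if (sum(abs(sums - max(sums)) < 1e-12) > 1) next   # unique optimum only
    t1 <- maxSssThreshold(pred, labels)
    t2 <- maxSssThreshold(-pred, 1 - labels)
    # the mirrored problem splits the scores at the same point
    expect_identical(which(pred >= t1), which(!(-pred >= t2)))
  }
})

test_that("evaluation scores match brute-force AUC and behave under randomness", {
  pred <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  labels <- c(0, 0, 0, 1, 1, 1)
  ev <- evaluateScores(pred, labels)
  expect_equal(ev$auc, 1)
  expect_equal(ev$aucPr, 1)
  expect_equal(ev$tss, 1)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    pred <- round(runif(n), 1)            # plenty of ties
    labels <- rbinom(n, 1, 0.5)
    if (!any(labels == 1) || !any(labels == 0)) next
    ev <- evaluateScores(pred, labels)
    pos <- pred[labels == 1]; neg <- pred[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(ev$auc, brute, tolerance = 1e-12)
  }

  set.seed(6)
  pred <- runif(2000); labels <- rbinom(2000, 1, 0.5)
  ev <- evaluateScores(pred, labels)
  expect_gt(ev$auc, 0.47)
  expect_lt(ev$auc, 0.53)

  # degenerate constant predictions: AUC 0.5, CBI missing
  evc <- evaluateScores(rep(0.4, 50), rbinom(50, 1, 0.5))
  expect_equal(evc$auc, 0.5)
  expect_true(is.na(evc$cbi))
})

test_that("the continuous Boyce index rewards rank-consistent suitability", {
  set.seed(11)
  bg <- runif(3000)
  pres <- sqrt(runif(800))       # density increasing with suitability
  expect_gt(continuousBoyce(pres, bg), 0.8)
  expect_lt(abs(continuousBoyce(runif(800), bg)), 0.6)
})

test_that("small ensembles: pair combinatorics, convexity, weight scaling", {
  arch <- fixArch()
  bio <- fixBio()
  retained <- subsetStack(fixFull(), c("bio1", "bio12", "hli"))
  sp <- defaultVirtualSpecies(bio)
  samp <- sampleVirtualOccurrences(sp$strong_niche, bio, arch, 150, seed = 42)
  occ <- dedupeOccurrences(samp$occurrences, arch@dem)
  pres <- occ[occ$species == "strong_niche", ]
  pas <- generatePseudoAbsences("strong_niche", occ, arch@dem, minDist = 5.5,
                                nSets = 1, nPerSet = 300, seed = 2)
  ens <- suppressWarnings(
    fitEsm("strong_niche", pres, pas, retained, blockSizeKm = 10,
           nFolds = 4, nRepeats = 1, learner = "glm", seed = 3))
  expect_equal(length(ens@pairModels), choose(3, 2))
  two <- subsetStack(fixFull(), c("bio1", "bio12"))
  ens2 <- suppressWarnings(
    fitEsm("strong_niche", pres, pas, two, blockSizeKm = 10,
           nFolds = 4, nRepeats = 1, learner = "glm", seed = 3))
  expect_equal(length(ens2@pairModels), 1)

  proj <- projectEnsemble(ens, retained)
  Xall <- stackValues(retained)
  cells <- attr(Xall, "cells")
  probs <- sapply(ens@pairModels, function(m) {
    L <- islesdm:::esmLearner(m$learner, 0)
    L$prob(m$model, Xall[, m$vars, drop = FALSE])
  })
  w <- vapply(ens@pairModels, `[[`, 1, "weight")
  pv <- gridValues(proj)[cells]
  expect_true(all(pv >= apply(probs, 1, min) - 1e-9))
  expect_true(all(pv <= apply(probs, 1, max) + 1e-9))

  scaled <- ens
  for (i in seq_along(scaled@pairModels))
    scaled@pairModels[[i]]$weight <- scaled@pairModels[[i]]$weight * 3
  projS <- projectEnsemble(scaled, retained)
  expect_lt(max(abs(gridValues(projS) - gridValues(proj)), na.rm = TRUE), 1e-9)

  # training-domain projection reproduces per-model training predictions
  single <- ens
  single@pairModels <- ens@pairModels[1]
  single@pairModels[[1]]$weight <- 1
  proj1 <- projectEnsemble(single, retained)
  m <- single@pairModels[[1]]
  L <- islesdm:::esmLearner(m$learner, 0)
  direct <- L$prob(m$model, Xall[, m$vars, drop = FALSE])
  expect_equal(gridValues(proj1)[cells], direct, tolerance = 1e-9)
})

test_that("null-model p-values respect their formula bounds", {
  res <- nullModelTest(-1, function(i) runif(1), nNull = 19, seed = 1)
  expect_equal(res$p, 1)
  res2 <- nullModelTest(2, function(i) runif(1), nNull = 99, seed = 1)
  expect_equal(res2$p, 0.01)
})
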