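test_that("clamping nullifies suitability exactly where predictors leave the envelope", {
  retained <- subsetStack(fixFull(), c("bio1", "bio12"))
  arch <- fixArch()
  bio <- fixBio()
  sp <- defaultVirtualSpecies(bio)
  samp <- sampleVirtualOccurrences(sp$strong_niche, bio, arch, 120, seed = 51)
  occ <- dedupeOccurrences(samp$occurrences, arch@dem)
  pres <- occ[occ$species == "strong_niche", ]
  pas <- generatePseudoAbsences("strong_niche", occ, arch@dem, 5.5, 1, 300,
                                seed = 1)
  ens <- suppressWarnings(fitEsm("strong_niche", pres, pas, retained,
                                 blockSizeKm = 10, nFolds = 4, nRepeats = 1,
                                 learner = "glm", seed = 2))
  suit <- projectEnsemble(ens, retained)
  cl <- clampSuitability(ens, retained, suit)
  # the training stack spans a superset of training cells: wherever the mask
  # is zero the suitability is untouched, elsewhere it is zeroed
  mask <- gridValues(cl$clampingMask)
  expect_true(all(mask[!is.na(mask)] <= ncol(ens@trainingRanges)))
  inside <- !is.na(mask) & mask == 0
  expect_equal(gridValues(cl$suitability)[inside], gridValues(suit)[inside])
  outside <- !is.na(mask) & mask > 0
  if (any(outside))
    expect_true(all(gridValues(cl$suitability)[outside] == 0))
  expect_true(all(gridValues(cl$suitability)[!is.na(mask)] <=
                  gridValues(suit)[!is.na(mask)] + 1e-12))

  # push one predictor above its training maximum in a known set of cells
  shifted <- retained
  b1 <- getLayer(retained, "bio1")
  hi <- ens@trainingRanges["max", "bio1"]
  v <- gridValues(b1)
  target <- which(!is.na(v))[1:25]
  v[target] <- hi + 5
  gridValues(b1) <- v
  shifted@layers[["bio1"]] <- b1
  suit2 <- projectEnsemble(ens, shifted)
  cl2 <- clampSuitability(ens, shifted, suit2)
  m2 <- gridValues(cl2$clampingMask)
  expect_true(all(m2[target] >= 1))
  expect_true(all(gridValues(cl2$suitability)[target] == 0))
})

test_that("binarization is monotone in the threshold", {
  set.seed(4)
  suit <- rasterGrid(matrix(runif(400), 20, 20), cellKm = 1)
  n <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t)
    sum(gridValues(binarizeSuitability(suit, t)$presence)), 1)
  expect_true(all(diff(n) <= 0))
})

test_that("ExDet components match the literal per-point definition", {
  set.seed(12)
  ref <- matrix(rnorm(400 * 5), 400, 5)
  proj <- matrix(rnorm(1000 * 5, sd = 1.4), 1000, 5)
  ex <- exDet(ref, proj)

  lo <- apply(ref, 2, min); hi <- apply(ref, 2, max); rng <- hi - lo
  mu <- colMeans(ref); cv <- cov(ref)
  d2max <- max(mahalanobis(ref, mu, cv))
  for (i in sample(1000, 200)) {
    nt1i <- 0
    for (j in 1:5)
      nt1i <- nt1i + min((proj[i, j] - lo[j]) / rng[j],
                         (hi[j] - proj[i, j]) / rng[j], 0)
    expect_equal(ex$nt1[i], nt1i, tolerance = 1e-12)
    if (nt1i == 0) {
      nt2i <- mahalanobis(proj[i, , drop = FALSE], mu, cv) / d2max
      expect_equal(ex$nt2[i], unname(nt2i), tolerance = 1e-12)
      expect_equal(ex$exdet[i], unname(nt2i), tolerance = 1e-12)
    } else {
      expect_equal(ex$exdet[i], nt1i, tolerance = 1e-12)
    }
  }
  expect_true(all(ex$nt1 <= 0))
  expect_true(all(ex$nt2[!is.na(ex$nt2)] >= 0))
  expect_gte(ex$analogueFraction, 0)
  expect_lte(ex$analogueFraction, 100)

  # the reference projected onto itself is fully analogue
  exSelf <- exDet(ref, ref)
  expect_equal(exSelf$analogueFraction, 100)
  # a point at the reference mean has no novelty of either type
  exMean <- exDet(ref, rbind(colMeans(ref)))
  expect_equal(exMean$nt1, 0)
  expect_equal(exMean$nt2, 0, tolerance = 1e-12)
  # 10% below one variable's range, inside the others
  pt <- colMeans(ref)
  pt[3] <- lo[3] - 0.1 * rng[3]
  expect_equal(exDet(ref, rbind(pt))$nt1, -0.1, tolerance = 1e-9)
  expect_error(exDet(cbind(ref[, 1], ref[, 1]), proj[, 1:2]), "singular|constant")
})

test_that("niche truncation index spans identity, half overlap and disjunction", {
  set.seed(13)
  a <- cbind(runif(400), runif(400))
  expect_lt(nicheTruncationIndex(a, a), 0.05)
  b <- cbind(runif(400, 5, 6), runif(400, 5, 6))
  expect_gt(nicheTruncationIndex(a, b), 0.95)
  # half-overlapping uniforms: half the mass is shared
  c1 <- cbind(runif(4000), runif(4000))
  c2 <- cbind(runif(4000) + 0.5, runif(4000))
  idx <- nicheTruncationIndex(c1, c2)
  expect_gt(idx, 0.35)
  expect_lt(idx, 0.62)
  expect_error(nicheTruncationIndex(cbind(rep(1, 20), 1:20),
                                    cbind(rep(1, 20), 1:20)), "variance")
})

test_that("range change accounting matches its definition under dispersal modes", {
  m0 <- matrix(0, 20, 20)
  cur <- m0; cur[1:10, 1:10] <- 1          # 100 current cells
  fut <- m0; fut[1:10, 1:5] <- 1           # keeps 50
  fut[1:10, 11:12] <- 1                    # 20 new cells adjacent to range
  curMap <- toyRange(cur); futMap <- toyRange(fut)

  same <- rangeChange(curMap, curMap, "buffered")
  expect_equal(same$changePct, 0)
  expect_equal(same$lossCells, 0)
  expect_equal(same$gainCells, 0)

  gone <- rangeChange(curMap, toyRange(m0), "buffered")
  expect_equal(gone$changePct, -100)

  none <- rangeChange(curMap, futMap, "none")
  expect_equal(none$gainCells, 0)
  expect_equal(none$changePct, -50)

  fullD <- rangeChange(curMap, futMap, "full")
  expect_equal(fullD$gainCells, 20)
  expect_equal(fullD$changePct, -30)

  buf <- rangeChange(curMap, futMap, "buffered", bufferKm = 1.5)
  expect_equal(buf$gainCells, 10)          # only the first adjacent column
  expect_equal(buf$changePct, -40)

  empty <- rangeChange(toyRange(m0), futMap, "buffered")
  expect_true(is.na(empty$changePct))
  expect_true(empty$flagged)
})
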