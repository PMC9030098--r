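#' Generate taxon-specific pseudo-absence sets
#'
#' Uniform sampling without replacement from land cells at least `minDist`
#' (great-circle km) from every presence of the species; sets are seeded
#' disjointly.
#'
#' @param species species identifier (used for seeding and bookkeeping).
#' @param occ occurrence data.frame (all species; filtered internally).
#' @param region land [RasterGrid-class] (nodata = sea).
#' @param minDist minimum distance from any presence, km (default 5.5).
#' @param nSets number of pseudo-absence sets.
#' @param nPerSet points per set.
#' @param seed integer seed.
#' @param allowFewer when TRUE, a shortfall of eligible cells shrinks
#'   `nPerSet` (with a warning) instead of failing; widespread species on
#'   small archipelagos can leave few cells beyond `minDist`.
#' @return list of data.frames (`lon`, `lat`, `cell`, `setId`).
#' @export
generatePseudoAbsences <- function(species, occ, region, minDist = 5.5,
                                   nSets = 5, nPerSet = 1000, seed = 1,
                                   allowFewer = FALSE) {
  pres <- occ[occ$species == species, , drop = FALSE]
  stopifnot(nrow(pres) >= 3)
  force(region)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  cells <- validCells(region)
  ll <- lonLatFromCell(region, cells)
  presCell <- cellFromLonLat(region, pres$lon, pres$lat)$cell
  dmin <- rep(Inf, length(cells))
  for (i in seq_len(nrow(pres)))
    dmin <- pmin(dmin, haversineKm(ll$lon, ll$lat, pres$lon[i], pres$lat[i]))
  eligible <- cells[dmin >= minDist & !(cells %in% presCell)]
  if (length(eligible) < nPerSet) {
    if (!allowFewer || length(eligible) < max(20, nrow(pres)))
      stop(sprintf(paste0("only %d eligible cells for %d pseudo-absences; ",
                          "reduce minDist or nPerSet"),
                   length(eligible), nPerSet))
    warning(sprintf("species '%s': only %d eligible cells; nPerSet reduced",
                    species, length(eligible)))
    nPerSet <- length(eligible)
  }
  lapply(seq_len(nSets), function(s) {
    set.seed(as.integer(seed) + 7919L * s)
    pick <- sample(eligible, nPerSet)
    pll <- lonLatFromCell(region, pick)
    data.frame(lon = pll$lon, lat = pll$lat, cell = pick, setId = s)
  })
}

#' Median spatial autocorrelation range of a predictor stack
#'
#' Per layer, an empirical semivariogram is computed on randomly sampled
#' cell pairs; the sill is the mean semivariance over the largest 25% of
#' lags and the range is the smallest lag-bin midpoint where the smoothed
#' semivariance reaches 95% of the sill. The median over layers is
#' returned (km). Flat layers are skipped with a warning.
#'
#' @param stack a [LayerStack-class].
#' @param nPairs cell pairs sampled per layer.
#' @param nBins number of lag bins.
#' @param seed integer seed.
#' @return median range in km; per-layer ranges as attribute `"perLayer"`.
#' @export
medianAutocorrelationRange <- function(stack, nPairs = 20000, nBins = 25,
                                       seed = 1) {
  stopifnot(length(stack) >= 1)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  g0 <- stack@layers[[1]]
  cc <- cellCentersXY(g0)
  ranges <- c()
  for (nm in layerNames(stack)) {
    g <- getLayer(stack, nm)
    cells <- validCells(g)
    if (length(cells) < 10) next
    if (var(g@values[cells]) < 1e-24) {
      warning(sprintf("layer '%s' is flat; skipped", nm))
      next
    }
    # stratified pairs: half global (sill), half local (short-lag resolution)
    nHalf <- floor(nPairs / 2)
    i1 <- sample(cells, nHalf, replace = TRUE)
    j1 <- sample(cells, nHalf, replace = TRUE)
    nr <- nrow(g@values)
    i2 <- sample(cells, nPairs - nHalf, replace = TRUE)
    off <- sample(-12:12, 2 * length(i2), replace = TRUE)
    r2 <- ((i2 - 1) %% nr) + 1 + off[seq_along(i2)]
    c2 <- ((i2 - 1) %/% nr) + 1 + off[-seq_along(i2)]
    okL <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(g@values)
    j2 <- (c2[okL] - 1) * nr + r2[okL]
    i2 <- i2[okL]
    okL2 <- !is.na(g@values[j2])
    i <- c(i1, i2[okL2]); j <- c(j1, j2[okL2])
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- sqrt((cc$x[i] - cc$x[j])^2 + (cc$y[i] - cc$y[j])^2)
    sv <- 0.5 * (g@values[i] - g@values[j])^2
    maxLag <- quantile(d, 0.95, names = FALSE)
    keep <- d <= maxLag
    cell <- g0@cellKm
    fine <- seq(0, min(12 * cell, maxLag), by = cell)
    breaks <- unique(c(fine, seq(max(fine), maxLag,
                                 length.out = max(2, nBins - length(fine)))))
    bins <- cut(d[keep], breaks = breaks, include.lowest = TRUE)
    gamma <- tapply(sv[keep], bins, mean)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    okb <- !is.na(gamma)
    gamma <- gamma[okb]; mids <- mids[okb]
    if (length(gamma) < 4) next
    sill <- mean(gamma[mids >= quantile(mids, 0.75, names = FALSE)])
    hit <- which(gamma >= 0.95 * sill)
    ranges[nm] <- if (length(hit)) mids[min(hit)] else max(mids)
  }
  if (!length(ranges)) stop("no usable layers for variogram ranges")
  structure(median(ranges), perLayer = ranges)
}

#' Assign points to spatial-block cross-validation folds
#'
#' Points are overlaid on a square lattice of side `blockSize` km with a
#' random origin; all points of a block share a fold. Blocks are dealt to
#' folds greedily (largest presence count first, to the fold with the
#' fewest presences; ties to the fold with fewer points, then lowest id),
#' so with `nFolds = 5` each fold's test share is approximately 20%.
#'
#' @param points data.frame with planar `x`, `y` (km) and `label` (1 =
#'   presence, 0 = absence).
#' @param blockSize lattice side, km.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed (controls the lattice origin).
#' @return list of class `BlockCV`: `fold` (per-point fold id), `block`
#'   (per-point block id), `foldOfBlock`, `blockSize`, `nFolds`, `origin`.
#' @export
assignBlocks <- function(points, blockSize, nFolds = 5, seed = 1) {
  stopifnot(blockSize > 0, nFolds >= 2)
  force(points)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  ox <- min(points$x) - runif(1) * blockSize
  oy <- min(points$y) - runif(1) * blockSize
  bi <- floor((points$x - ox) / blockSize)
  bj <- floor((points$y - oy) / blockSize)
  block <- paste(bi, bj, sep = "_")
  ub <- unique(block)
  presCount <- vapply(ub, function(b) sum(points$label[block == b] == 1), 1)
  totCount <- vapply(ub, function(b) sum(block == b), 1)
  if (sum(presCount > 0) == 1 && sum(presCount) > 0)
    stop("all presences fall in a single block; degenerate split rejected")
  ord <- order(-presCount, -totCount, ub)
  foldPres <- numeric(nFolds); foldTot <- numeric(nFolds)
  foldOfBlock <- setNames(integer(length(ub)), ub)
  for (b in ub[ord]) {
    # presence blocks balance presences; absence-only blocks balance size
    target <- if (presCount[b] > 0)
      order(foldPres, foldTot, seq_len(nFolds))[1]
    else order(foldTot, foldPres, seq_len(nFolds))[1]
    foldOfBlock[b] <- target
    foldPres[target] <- foldPres[target] + presCount[b]
    foldTot[target] <- foldTot[target] + totCount[b]
  }
  structure(list(fold = unname(foldOfBlock[block]), block = block,
                 foldOfBlock = foldOfBlock, blockSize = blockSize,
                 nFolds = nFolds, origin = c(ox, oy)),
            class = "BlockCV")
}

#' True Skill Statistic from a confusion matrix
#'
#' `TSS = sensitivity + specificity - 1`.
#'
#' @param tp,fp,fn,tn confusion-matrix counts.
#' @return numeric in `[-1, 1]`.
#' @export
tss <- function(tp, fp, fn, tn) {
  if (tp + fn == 0 || tn + fp == 0)
    stop("TSS undefined: one class is empty")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# TSS of predictions at a threshold (presence when pred >= thr)
tssAt <- function(pred, labels, thr) {
  p <- pred >= thr
  tss(sum(p & labels == 1), sum(p & labels == 0),
      sum(!p & labels == 1), sum(!p & labels == 0))
}

#' maxSSS binarization threshold
#'
#' Evaluates sensitivity + specificity at every midpoint between consecutive
#' distinct sorted scores plus the two extremes, and returns the threshold
#' with the maximal sum (ties resolved to the lowest threshold). Presence is
#' predicted when score `>= threshold`.
#'
#' @param pred suitability scores.
#' @param labels 0/1 labels (both classes present).
#' @return the threshold.
#' @export
maxSssThreshold <- function(pred, labels) {
  stopifnot(any(labels == 1), any(labels == 0))
  s <- sort(unique(pred))
  if (length(s) < 2) stop("all scores identical; threshold undefined")
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  sums <- vapply(cand, function(t) {
    p <- pred >= t
    sum(p & labels == 1) / np + sum(!p & labels == 0) / nn
  }, 1)
  cand[which(sums >= max(sums) - 1e-12)[1]]
}

#' Evaluate suitability predictions against presence/absence labels
#'
#' AUC by the rank (Mann-Whitney) statistic with half credit for ties;
#' AUC-PR by precision-recall step integration; TSS at the maxSSS threshold;
#' the Continuous Boyce Index as the Spearman correlation between the
#' predicted-to-expected presence ratio and the window midpoint over 100
#' moving windows of width 10% of the suitability range (presences vs
#' background); and the expected calibration error over 10 equal-width bins.
#'
#' @param pred suitability scores for labelled points.
#' @param labels 0/1 labels.
#' @param background suitability scores of background cells for the CBI
#'   (default: the absence scores).
#' @return list of class `EvalReport`: `auc`, `aucPr`, `tss`, `cbi`, `ece`,
#'   `thresholdUsed`, `nTest`.
#' @export
evaluateScores <- function(pred, labels, background = NULL) {
  stopifnot(any(labels == 1), any(labels == 0))
  if (is.null(background)) background <- pred[labels == 0]
  np <- sum(labels == 1); nn <- sum(labels == 0)

  r <- rank(pred)
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  # precision-recall step integration over distinct score groups (desc)
  ord <- order(pred, decreasing = TRUE)
  lab <- labels[ord]; sc <- pred[ord]
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab == 1); allCum <- seq_along(lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tpCum[last] / np
  precision <- tpCum[last] / allCum[last]
  aucPr <- sum(diff(c(0, recall)) * precision)

  thr <- tryCatch(maxSssThreshold(pred, labels), error = function(e) NA_real_)
  tssVal <- if (is.na(thr)) NA_real_ else tssAt(pred, labels, thr)
  if (is.na(thr)) auc <- 0.5

  cbi <- continuousBoyce(pred[labels == 1], background)

  bins <- pmin(floor(pred * 10) + 1, 10)
  ece <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    ece <- ece + sum(sel) / length(pred) *
      abs(mean(labels[sel]) - mean(pred[sel]))
  }

  structure(list(auc = auc, aucPr = aucPr, tss = tssVal, cbi = cbi, ece = ece,
                 thresholdUsed = thr, nTest = length(pred)),
            class = "EvalReport")
}

#' Continuous Boyce Index
#'
#' @param presScores suitability at presences.
#' @param bgScores suitability at background cells.
#' @param nWindows number of moving windows (default 100).
#' @param widthFrac window width as a fraction of the score range.
#' @return Spearman correlation of P/E ratio with window midpoint, or `NA`
#'   when degenerate.
#' @export
continuousBoyce <- function(presScores, bgScores, nWindows = 100,
                            widthFrac = 0.1) {
  rng <- range(c(presScores, bgScores))
  if (diff(rng) < 1e-12) return(NA_real_)
  w <- widthFrac * diff(rng)
  starts <- seq(rng[1], rng[2] - w, length.out = nWindows)
  pe <- mids <- numeric(0)
  for (s in starts) {
    p <- mean(presScores >= s & presScores <= s + w)
    e <- mean(bgScores >= s & bgScores <= s + w)
    if (e > 0) { pe <- c(pe, p / e); mids <- c(mids, s + w / 2) }
  }
  if (length(pe) < 3 || var(pe) < 1e-24) return(NA_real_)
  cor(pe, mids, method = "spearman")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (n = %d): AUC %.3f, AUC-PR %.3f, TSS %.3f, CBI %s, ECE %.3f\n",
              x$nTest, x$auc, x$aucPr, x$tss,
              if (is.na(x$cbi)) "NA" else sprintf("%.3f", x$cbi), x$ece))
  invisible(x)
}

# --- learners ---------------------------------------------------------------

esmLearner <- function(learner, nTrees) {
  switch(learner,
    rf = list(
      fit = function(X, y)
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = nTrees),
      prob = function(model, X)
        unname(predict(model, X, type = "prob")[, "1"])),
    glm = list(
      fit = function(X, y) {
        df <- as.data.frame(X); df$.y <- y
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      },
      prob = function(model, X)
        unname(predict(model, as.data.frame(X), type = "response"))),
    stop("unknown learner: ", learner))
}

#' Fit an Ensemble of Small Models for one species
#'
#' For every unordered pair of retained predictors and every pseudo-absence
#' set, a binary classifier (Random Forest by default) is fitted. Its weight
#' is the mean cross-validated TSS over spatial-block folds and repeats
#' (each repeat re-draws the block lattice origin), floored at 0. Ensemble
#' suitability is the weight-normalized mean of the pair-model
#' probabilities. The ensemble's own skill (`ensembleTss`) is the mean over
#' sets, repeats and folds of the ensemble TSS on held-out blocks (each fold
#' thresholded at its own maxSSS); the binarization threshold is fitted on
#' the cross-validation ensemble predictions pooled over repeats.
#'
#' @param species species identifier.
#' @param presences data.frame of the species' presences (`lon`, `lat`).
#' @param paSets list of pseudo-absence data.frames
#'   (from [generatePseudoAbsences()]).
#' @param predictors retained predictor [LayerStack-class] (>= 2 layers).
#' @param blockSizeKm spatial-block side for cross-validation, km.
#' @param nFolds folds per repeat (default 5, i.e. 80:20 splits).
#' @param nRepeats block-lattice repeats (default 10).
#' @param learner `"rf"` (Random Forest) or `"glm"`.
#' @param nTrees trees per Random Forest (default 500).
#' @param tssMin downstream admission gate on ensemble TSS (recorded, not
#'   enforced here).
#' @param seed integer seed.
#' @return An [EsmEnsemble-class]. When every pair weight is 0 the species
#'   is flagged unmodellable (`modellable = FALSE`) with a warning.
#' @export
fitEsm <- function(species, presences, paSets, predictors, blockSizeKm = 5.5,
                   nFolds = 5, nRepeats = 10, learner = c("rf", "glm"),
                   nTrees = 500, tssMin = 0.8, seed = 1) {
  learner <- match.arg(learner)
  stopifnot(length(predictors) >= 2)
  L <- esmLearner(learner, nTrees)
  grid <- predictors@layers[[1]]
  pairs <- combn(layerNames(predictors), 2, simplify = FALSE)

  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  presCells <- cellFromLonLat(grid, presences$lon, presences$lat)$cell
  presX <- stackValues(predictors, presCells)
  presXY <- lonLatToXY(grid, presences$lon, presences$lat)
  okPres <- complete.cases(presX)   # coastal cells can lack topographic values
  presX <- presX[okPres, , drop = FALSE]
  presXY <- presXY[okPres, , drop = FALSE]
  presences <- presences[okPres, , drop = FALSE]
  if (nrow(presences) < 3)
    stop(sprintf("species '%s': fewer than 3 presences with complete predictors",
                 species))

  allTrainCells <- c(presCells[okPres], unlist(lapply(paSets, `[[`, "cell")))
  allX <- stackValues(predictors, allTrainCells)
  trainingRanges <- rbind(min = apply(allX, 2, min, na.rm = TRUE),
                          max = apply(allX, 2, max, na.rm = TRUE))

  pairModels <- list()
  cvLabel <- cvPredPool <- NULL
  foldTss <- c()   # per set x repeat x fold ensemble TSS

  for (s in seq_along(paSets)) {
    pa <- paSets[[s]]
    paX <- stackValues(predictors, pa$cell)
    okPa <- complete.cases(paX)
    pa <- pa[okPa, , drop = FALSE]
    paX <- paX[okPa, , drop = FALSE]
    paXY <- lonLatToXY(grid, pa$lon, pa$lat)
    y <- c(rep(1, nrow(presences)), rep(0, nrow(pa)))
    pts <- data.frame(x = c(presXY$x, paXY$x), y = c(presXY$y, paXY$y),
                      label = y)
    Xall <- rbind(presX, paX)

    # fold assignments per repeat (shared across pairs within this set)
    folds <- lapply(seq_len(nRepeats), function(r)
      assignBlocks(pts, blockSizeKm, nFolds,
                   seed = as.integer(seed) + 131L * s + 17L * r))

    # cross-validated predictions per pair and repeat
    cvp <- array(NA_real_, c(length(y), length(pairs), nRepeats))
    weights <- numeric(length(pairs))
    for (k in seq_along(pairs)) {
      vars <- pairs[[k]]
      Xp <- Xall[, vars, drop = FALSE]
      tssVals <- c()
      for (r in seq_len(nRepeats)) {
        fold <- folds[[r]]$fold
        for (f in sort(unique(fold))) {
          test <- fold == f
          if (sum(y[test] == 1) < 1 || sum(y[test] == 0) < 1 ||
              sum(y[!test] == 1) < 2 || sum(y[!test] == 0) < 2) next
          fit <- L$fit(Xp[!test, , drop = FALSE], y[!test])
          p <- L$prob(fit, Xp[test, , drop = FALSE])
          thr <- tryCatch(maxSssThreshold(p, y[test]),
                          error = function(e) NA_real_)
          if (!is.na(thr)) tssVals <- c(tssVals, tssAt(p, y[test], thr))
          cvp[test, k, r] <- p
        }
      }
      w <- max(0, mean(tssVals, na.rm = TRUE))
      if (!is.finite(w)) w <- 0
      weights[k] <- w
      finalFit <- L$fit(Xp, y)
      pairModels[[length(pairModels) + 1]] <-
        list(vars = vars, set = s, model = finalFit, weight = w,
             learner = learner)
    }

    # weight-combined CV ensemble predictions; fold-level ensemble skill
    if (any(weights > 0)) {
      for (r in seq_len(nRepeats)) {
        pr <- cvp[, , r, drop = FALSE][, , 1, drop = FALSE]
        dim(pr) <- dim(cvp)[1:2]
        ok <- !is.na(pr)
        num <- rowSums(sweep(ifelse(ok, pr, 0), 2, weights, `*`))
        den <- as.vector(ifelse(ok, 1, 0) %*% weights)
        ens <- ifelse(den > 0, num / den, NA)
        fold <- folds[[r]]$fold
        for (f in sort(unique(fold))) {
          test <- fold == f & !is.na(ens)
          if (sum(y[test] == 1) < 1 || sum(y[test] == 0) < 1) next
          thrF <- tryCatch(maxSssThreshold(ens[test], y[test]),
                           error = function(e) NA_real_)
          if (!is.na(thrF))
            foldTss <- c(foldTss, tssAt(ens[test], y[test], thrF))
        }
        keep <- !is.na(ens)
        cvLabel <- c(cvLabel, y[keep])
        cvPredPool <- c(cvPredPool, ens[keep])
      }
    }
  }

  cvPred <- data.frame(label = as.numeric(cvLabel),
                       pred = as.numeric(cvPredPool))

  allW <- vapply(pairModels, `[[`, 1, "weight")
  modellable <- any(allW > 0)
  ensTss <- if (length(foldTss)) mean(foldTss) else NA_real_
  thr <- NA_real_
  if (modellable && nrow(cvPred) &&
      any(cvPred$label == 1) && any(cvPred$label == 0))
    thr <- tryCatch(maxSssThreshold(cvPred$pred, cvPred$label),
                    error = function(e) NA_real_)
  if (!modellable)
    warning(sprintf("species '%s': every pair model has zero skill; unmodellable",
                    species))

  new("EsmEnsemble", species = species, pairModels = pairModels,
      trainingRanges = trainingRanges, ensembleTss = ensTss,
      threshold = if (is.na(thr)) 0.5 else thr, cvPred = cvPred,
      modellable = modellable)
}

#' @export
setGeneric("pairWeights", function(object) standardGeneric("pairWeights"))
#' Pair-model weights of an ensemble
#' @param object an [EsmEnsemble-class].
#' @return data.frame with `var1`, `var2`, `set`, `weight`.
#' @rdname pairWeights
#' @export
setMethod("pairWeights", "EsmEnsemble", function(object) {
  do.call(rbind, lapply(object@pairModels, function(m)
    data.frame(var1 = m$vars[1], var2 = m$vars[2], set = m$set,
               weight = m$weight)))
})

#' @export
setGeneric("ensembleTss", function(object) standardGeneric("ensembleTss"))
#' Cross-validated ensemble TSS
#' @param object an [EsmEnsemble-class].
#' @rdname ensembleTss
#' @export
setMethod("ensembleTss", "EsmEnsemble", function(object) object@ensembleTss)

setMethod("show", "EsmEnsemble", function(object) {
  w <- vapply(object@pairModels, `[[`, 1, "weight")
  cat(sprintf("EsmEnsemble '%s': %d pair models (%d with weight > 0), ensemble TSS %s\n",
              object@species, length(w), sum(w > 0),
              if (is.na(object@ensembleTss)) "NA"
              else sprintf("%.3f", object@ensembleTss)))
  invisible(object)
})

#' Null-model significance of an observed ensemble skill
#'
#' Recomputes the skill statistic on `nNull` datasets with presence
#' locations resampled at random (the caller supplies the resample-and-score
#' function, typically wrapping [fitEsm()]), and returns
#' `p = (1 + #(null >= observed)) / (nNull + 1)`.
#'
#' @param observedTss observed ensemble TSS.
#' @param nullTssFun function(i) returning the skill of the i-th null refit.
#' @param nNull number of null datasets (>= 19; default 99).
#' @param seed integer seed (set before the sequence of null fits).
#' @return list: `p`, `nullTss`, `observedTss`.
#' @export
nullModelTest <- function(observedTss, nullTssFun, nNull = 99, seed = 1) {
  stopifnot(nNull >= 19)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  nullTss <- vapply(seq_len(nNull), function(i) nullTssFun(i), 1)
  p <- (1 + sum(nullTss >= observedTss)) / (nNull + 1)
  list(p = p, nullTss = nullTss, observedTss = observedTss)
}

#' Null resampler for ensemble skill on a landscape
#'
#' Convenience wrapper producing the `nullTssFun` needed by
#' [nullModelTest()]: each call draws the same number of presences uniformly
#' from land cells and refits the ensemble with the same settings.
#'
#' @param nPres number of presences per null dataset.
#' @param region land [RasterGrid-class].
#' @param paSets pseudo-absence sets reused across nulls.
#' @param predictors retained predictor stack.
#' @param ... further arguments passed to [fitEsm()].
#' @return function(i) returning a null ensemble TSS.
#' @export
makeNullTssFun <- function(nPres, region, paSets, predictors, ...) {
  cells <- validCells(region)
  extra <- list(...)
  function(i) {
    # presences and the per-fit seed are drawn from the caller's RNG stream
    pick <- sample(cells, nPres)
    args <- extra
    if (is.null(args$seed)) args$seed <- sample.int(1000000L, 1)
    ll <- lonLatFromCell(region, pick)
    ens <- suppressWarnings(do.call(fitEsm, c(
      list("null", data.frame(lon = ll$lon, lat = ll$lat), paSets,
           predictors), args)))
    if (is.na(ens@ensembleTss)) 0 else ens@ensembleTss
  }
}
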