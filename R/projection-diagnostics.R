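#' Project an ensemble onto an environment stack
#'
#' Weight-normalized mean of the pair-model probabilities per cell; nodata
#' propagates. A convex combination: the projection lies between the
#' cellwise min and max of the pair probabilities.
#'
#' @param ens an [EsmEnsemble-class].
#' @param env [LayerStack-class] containing every predictor used by `ens`.
#' @return suitability [RasterGrid-class] in `[0, 1]`.
#' @export
projectEnsemble <- function(ens, env) {
  used <- unique(unlist(lapply(ens@pairModels, `[[`, "vars")))
  missing <- setdiff(used, layerNames(env))
  if (length(missing))
    stop("missing predictor(s) in stack: ", paste(missing, collapse = ", "))
  grid <- env@layers[[1]]
  X <- stackValues(subsetStack(env, used))
  cells <- attr(X, "cells")
  num <- rep(0, length(cells)); den <- 0
  for (m in ens@pairModels) {
    if (m$weight <= 0) next
    L <- esmLearner(m$learner, 0)
    p <- L$prob(m$model, X[, m$vars, drop = FALSE])
    num <- num + m$weight * p
    den <- den + m$weight
  }
  if (den == 0) stop(sprintf("ensemble '%s' has no positive-weight models",
                             ens@species))
  out <- sameGrid(grid, NA_real_)
  out@values[cells] <- num / den
  out
}

#' Clamp projected suitability outside the training envelope
#'
#' The clamping mask counts, per cell, how many predictors fall outside
#' their training (min, max); suitability is nullified wherever the count is
#' non-zero.
#'
#' @param ens an [EsmEnsemble-class] (provides training ranges).
#' @param env projection [LayerStack-class].
#' @param suitability projected suitability [RasterGrid-class].
#' @return list: `suitability` (clamped) and `clampingMask` (count raster).
#' @export
clampSuitability <- function(ens, env, suitability) {
  rng <- ens@trainingRanges
  stopifnot(!is.null(rng), nrow(rng) == 2)
  used <- intersect(colnames(rng), layerNames(env))
  X <- stackValues(subsetStack(env, used))
  cells <- attr(X, "cells")
  cnt <- rep(0L, length(cells))
  for (nm in used)
    cnt <- cnt + as.integer(X[, nm] < rng["min", nm] | X[, nm] > rng["max", nm])
  mask <- sameGrid(suitability, NA_real_)
  mask@values[cells] <- cnt
  out <- suitability
  bad <- which(mask@values > 0)
  out@values[bad] <- 0
  list(suitability = out, clampingMask = mask)
}

#' Binarize a suitability map at a threshold
#'
#' @param suitability suitability [RasterGrid-class].
#' @param threshold presence when suitability `>= threshold`.
#' @param species,scenario labels recorded in the result.
#' @return list of class `BinaryRangeMap`: `presence` (0/1 raster),
#'   `species`, `scenario`, `threshold`.
#' @export
binarizeSuitability <- function(suitability, threshold, species = "",
                                scenario = "baseline") {
  pres <- sameGrid(suitability, ifelse(is.na(suitability@values), NA,
                                       as.numeric(suitability@values >= threshold)))
  structure(list(presence = pres, species = species, scenario = scenario,
                 threshold = threshold), class = "BinaryRangeMap")
}

#' @export
print.BinaryRangeMap <- function(x, ...) {
  cat(sprintf("BinaryRangeMap '%s' (%s): %d presence cells (threshold %.3f)\n",
              x$species, x$scenario, sum(x$presence@values > 0, na.rm = TRUE),
              x$threshold))
  invisible(x)
}

#' ExDet extrapolation metrics and %N
#'
#' Univariate novelty `NT1` per point is the sum over variables of
#' `min(x - min, max - x, 0) / (max - min)` (0 inside the reference range,
#' negative outside). For points with `NT1 = 0`, combinatorial novelty
#' `NT2` is the Mahalanobis distance to the reference mean/covariance
#' divided by the maximum Mahalanobis distance within the reference set
#' (`NT2 > 1` flags novel combinations). The combined ExDet field is `NT1`
#' where `NT1 < 0`, else `NT2`; analogue cells have `NT1 = 0` and
#' `NT2 <= 1`. `%N` is the percentage of reference points whose Gower
#' distance to a projection point is at most the reference set's median
#' nearest-neighbour Gower distance.
#'
#' @param reference matrix of reference (training-domain) environments.
#' @param projection matrix of projected environments (same columns).
#' @param maxRef cap on reference rows used for `%N` (seeded subsample).
#' @param seed seed for the `%N` subsample.
#' @return list of class `ExtrapolationReport`: `nt1`, `nt2`, `exdet`,
#'   `pctNearby` (per projection point), `analogueFraction` (percent).
#' @export
exDet <- function(reference, projection, maxRef = 2000, seed = 1) {
  reference <- as.matrix(reference); projection <- as.matrix(projection)
  p <- ncol(reference)
  stopifnot(ncol(projection) == p, nrow(reference) >= p + 2)
  lo <- apply(reference, 2, min); hi <- apply(reference, 2, max)
  rng <- hi - lo
  if (any(rng <= 0)) stop("reference has a constant variable; drop it first")

  ud <- sweep(sweep(projection, 2, lo), 2, rng, "/")         # (x-min)/range
  udHi <- sweep(sweep(-projection, 2, -hi), 2, rng, "/")     # (max-x)/range
  nt1 <- unname(rowSums(pmin(pmin(ud, udHi), 0)))

  cv <- cov(reference)
  ok <- tryCatch({ solve(cv); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular reference covariance; reduce predictors")
  mu <- colMeans(reference)
  d2ref <- mahalanobis(reference, mu, cv)
  d2max <- max(d2ref)
  nt2 <- rep(NA_real_, nrow(projection))
  inRange <- nt1 >= -1e-12
  nt1[inRange] <- 0
  if (any(inRange))
    nt2[inRange] <- mahalanobis(projection[inRange, , drop = FALSE], mu, cv) /
      d2max
  exdet <- ifelse(nt1 < 0, nt1, nt2)
  analogue <- 100 * mean(inRange & nt2 <= 1, na.rm = FALSE)

  # %N with Gower distance (range-normalized mean absolute difference)
  refN <- reference
  if (nrow(refN) > maxRef) {
    oldSeed <- pushSeed(seed)
    on.exit(restoreRNG(oldSeed), add = TRUE)
    refN <- refN[sample(nrow(refN), maxRef), , drop = FALSE]
  }
  refScaled <- sweep(refN, 2, rng, "/")
  projScaled <- sweep(projection, 2, rng, "/")
  nnRef <- vapply(seq_len(nrow(refScaled)), function(i) {
    d <- rowMeans(abs(sweep(refScaled[-i, , drop = FALSE], 2,
                            refScaled[i, ])))
    min(d)
  }, 1)
  eps <- median(nnRef)
  pctN <- vapply(seq_len(nrow(projScaled)), function(i) {
    d <- rowMeans(abs(sweep(refScaled, 2, projScaled[i, ])))
    100 * mean(d <= eps)
  }, 1)

  structure(list(nt1 = nt1, nt2 = nt2, exdet = exdet, pctNearby = pctN,
                 analogueFraction = analogue),
            class = "ExtrapolationReport")
}

#' @export
print.ExtrapolationReport <- function(x, ...) {
  cat(sprintf("ExtrapolationReport: %.2f%% analogue; NT1 in [%.3g, 0], NT2 max %.3g\n",
              x$analogueFraction, min(x$nt1), max(x$nt2, na.rm = TRUE)))
  invisible(x)
}

#' ExDet between two environment stacks
#'
#' @param refStack reference [LayerStack-class] (e.g. baseline climate).
#' @param projStack projection [LayerStack-class] (e.g. a future scenario).
#' @param layers layer names to use (default: all shared).
#' @param ... passed to [exDet()].
#' @return An `ExtrapolationReport` with raster versions of `nt1`, `nt2`,
#'   `exdet` and `pctNearby` attached as `rasters`.
#' @export
exDetStacks <- function(refStack, projStack, layers = NULL, ...) {
  if (is.null(layers))
    layers <- intersect(layerNames(refStack), layerNames(projStack))
  ref <- stackValues(subsetStack(refStack, layers))
  proj <- stackValues(subsetStack(projStack, layers))
  cells <- attr(proj, "cells")
  rep <- exDet(ref, proj, ...)
  grid <- projStack@layers[[1]]
  mk <- function(v) { g <- sameGrid(grid, NA_real_); g@values[cells] <- v; g }
  rep$rasters <- list(nt1 = mk(rep$nt1), nt2 = mk(rep$nt2),
                      exdet = mk(rep$exdet), pctNearby = mk(rep$pctNearby))
  rep
}

#' Niche truncation index
#'
#' Both samples are projected onto the first two principal axes of the
#' pooled standardized data; kernel-smoothed densities (shared bandwidth)
#' are normalized to sum 1 on a common lattice, and the index is
#' `1 - Schoener's D = 0.5 * sum |z_study - z_full|`: 0 when the study-area
#' sample spans the full niche, near 1 when it captures a disjoint part.
#'
#' @param studyEnv matrix of environments at study-area occurrences.
#' @param fullEnv matrix of environments at full-range occurrences.
#' @param gridBins lattice resolution (default 100).
#' @return index in `[0, 1]`.
#' @export
nicheTruncationIndex <- function(studyEnv, fullEnv, gridBins = 100) {
  studyEnv <- as.matrix(studyEnv); fullEnv <- as.matrix(fullEnv)
  stopifnot(nrow(studyEnv) >= 10, nrow(fullEnv) >= 10)
  pooled <- rbind(studyEnv, fullEnv)
  sds <- apply(pooled, 2, sd)
  if (any(sds < 1e-12)) stop("zero-variance environmental variable")
  Z <- scale(pooled)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(Z))
  S <- pc$x[, 1:k, drop = FALSE]
  a <- S[seq_len(nrow(studyEnv)), , drop = FALSE]
  b <- S[-seq_len(nrow(studyEnv)), , drop = FALSE]
  if (k == 1) { a <- cbind(a, 0); b <- cbind(b, 0) }
  lims <- c(range(S[, 1]), if (k > 1) range(S[, 2]) else c(-1, 1))
  lims <- lims + c(-1, 1, -1, 1) * 0.05 * c(diff(lims[1:2]), diff(lims[1:2]),
                                            diff(lims[3:4]), diff(lims[3:4]))
  bw <- c(max(MASS::bandwidth.nrd(S[, 1]), 1e-6),
          max(if (k > 1) MASS::bandwidth.nrd(S[, 2]) else 1, 1e-6))
  da <- MASS::kde2d(a[, 1], a[, 2], h = bw, n = gridBins, lims = lims)
  db <- MASS::kde2d(b[, 1], b[, 2], h = bw, n = gridBins, lims = lims)
  za <- da$z / sum(da$z)
  zb <- db$z / sum(db$z)
  0.5 * sum(abs(za - zb))
}

#' Range change between current and future binary maps
#'
#' Loss = current and not future; raw gain = future and not current, masked
#' by the dispersal assumption: no gain (`"none"`), gain only within
#' `bufferKm` of the current range (`"buffered"`), or unrestricted
#' (`"full"`). `changePct = 100 (gain - loss) / current`.
#'
#' @param current,future `BinaryRangeMap`s on aligned grids, same species.
#' @param dispersalMode `"buffered"` (default), `"none"` or `"full"`.
#' @param bufferKm buffer radius for `"buffered"` (default 2 cell sizes).
#' @return list of class `RangeChange`: `lossCells`, `gainCells`,
#'   `stableCells`, `currentCells`, `futureCells`, `changePct`,
#'   `dispersalMode`; `changePct` is `NA` (flagged) for an empty current
#'   range.
#' @export
rangeChange <- function(current, future,
                        dispersalMode = c("buffered", "none", "full"),
                        bufferKm = NULL) {
  dispersalMode <- match.arg(dispersalMode)
  checkAligned(current$presence, future$presence)
  if (!identical(current$species, future$species))
    stop("range maps belong to different species")
  cur <- current$presence@values > 0
  fut <- future$presence@values > 0
  cur[is.na(cur)] <- FALSE; fut[is.na(fut)] <- FALSE
  if (is.null(bufferKm)) bufferKm <- 2 * current$presence@cellKm

  nCur <- sum(cur)
  loss <- cur & !fut
  gainRaw <- fut & !cur
  gain <- switch(dispersalMode,
    none = gainRaw & FALSE,
    full = gainRaw,
    buffered = {
      if (!nCur || !any(gainRaw)) gainRaw & FALSE
      else {
        cc <- cellCentersXY(current$presence)
        curPts <- cbind(cc$x[cur], cc$y[cur])
        g <- which(gainRaw)
        keep <- vapply(g, function(cell) {
          min((cc$x[cell] - curPts[, 1])^2 + (cc$y[cell] - curPts[, 2])^2) <=
            bufferKm^2
        }, TRUE)
        out <- gainRaw & FALSE
        out[g[keep]] <- TRUE
        out
      }
    })
  stable <- cur & fut
  res <- list(lossCells = sum(loss), gainCells = sum(gain),
              stableCells = sum(stable), currentCells = nCur,
              futureCells = sum(stable) + sum(gain),
              changePct = if (nCur == 0) NA_real_
                          else 100 * (sum(gain) - sum(loss)) / nCur,
              dispersalMode = dispersalMode, flagged = nCur == 0)
  structure(res, class = "RangeChange")
}

#' @export
print.RangeChange <- function(x, ...) {
  cat(sprintf("RangeChange (%s dispersal): %s%% (loss %d, gain %d, stable %d of %d)\n",
              x$dispersalMode,
              if (is.na(x$changePct)) "NA" else sprintf("%+.1f", x$changePct),
              x$lossCells, x$gainCells, x$stableCells, x$currentCells))
  invisible(x)
}
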