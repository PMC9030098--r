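#' Stack binary range maps into diversity surfaces
#'
#' Species richness (SR) is the cellwise presence count; weighted endemism
#' (WE) sums the inverse range sizes of the species present, so WE summed
#' over all cells equals the number of species with a non-empty range;
#' corrected weighted endemism (CWE) is `WE / SR` where `SR > 0`, else 0.
#'
#' @param ranges list of `BinaryRangeMap`s on aligned grids (one species
#'   each). Species with empty ranges are excluded with a warning.
#' @param scenario label recorded in the result.
#' @return list of class `DiversityMaps`: `sr`, `we`, `cwe`
#'   ([RasterGrid-class]s), `scenario`, `nSpecies` (with non-empty range).
#' @export
stackDiversity <- function(ranges, scenario = "baseline") {
  stopifnot(length(ranges) >= 1)
  g0 <- ranges[[1]]$presence
  sr <- matrix(0, nrow(g0@values), ncol(g0@values))
  we <- matrix(0, nrow(g0@values), ncol(g0@values))
  n <- 0
  for (rm in ranges) {
    checkAligned(g0, rm$presence)
    pres <- rm$presence@values > 0 & !is.na(rm$presence@values)
    size <- sum(pres)
    if (size == 0) {
      warning(sprintf("species '%s' has an empty range; excluded", rm$species))
      next
    }
    n <- n + 1
    sr <- sr + pres
    we <- we + pres / size
  }
  cwe <- ifelse(sr > 0, we / pmax(sr, 1), 0)
  nodata <- is.na(g0@values)
  sr[nodata] <- NA; we[nodata] <- NA; cwe[nodata] <- NA
  structure(list(sr = sameGrid(g0, sr), we = sameGrid(g0, we),
                 cwe = sameGrid(g0, cwe), scenario = scenario, nSpecies = n),
            class = "DiversityMaps")
}

#' @export
print.DiversityMaps <- function(x, ...) {
  cat(sprintf("DiversityMaps (%s): %d species; max SR %d; sum WE %.6g\n",
              x$scenario, x$nSpecies, max(x$sr@values, na.rm = TRUE),
              sum(x$we@values, na.rm = TRUE)))
  invisible(x)
}

#' L1 hotspot cells of a diversity metric
#'
#' Hotspots are the valid cells with value at or above the empirical
#' `quantile` (inverse-CDF convention, `type = 1`); ties at the cutoff are
#' all included, so the selection is deterministic and never drops a
#' top-scoring cell. Because the rule is rank-based it is invariant under
#' monotone transforms of the metric.
#'
#' @param metricMap metric [RasterGrid-class] (>= 100 valid cells).
#' @param quantile hotspot quantile (default 0.99, the top 1%).
#' @param dem optional DEM for attaching cell elevations.
#' @param metric,scenario labels recorded in the result.
#' @return list of class `HotspotSet`: `cells` (data.frame `cell`, `x`, `y`,
#'   `lon`, `lat`, `value`, `elevation`), `cutoff`, `quantile`, `metric`,
#'   `scenario`, `nValid`.
#' @export
l1Hotspots <- function(metricMap, quantile = 0.99, dem = NULL,
                       metric = "SR", scenario = "baseline") {
  cells <- validCells(metricMap)
  if (length(cells) < 100) stop("need at least 100 valid cells")
  v <- metricMap@values[cells]
  if (diff(range(v)) < 1e-24) stop("constant metric map; hotspots undefined")
  cutoff <- stats::quantile(v, quantile, type = 1, names = FALSE)
  sel <- v >= cutoff
  ll <- lonLatFromCell(metricMap, cells[sel])
  out <- data.frame(cell = cells[sel], x = ll$x, y = ll$y, lon = ll$lon,
                    lat = ll$lat, value = v[sel])
  out$elevation <- if (is.null(dem)) NA_real_ else dem@values[out$cell]
  structure(list(cells = out, cutoff = cutoff, quantile = quantile,
                 metric = metric, scenario = scenario,
                 nValid = length(cells)),
            class = "HotspotSet")
}

#' @export
print.HotspotSet <- function(x, ...) {
  cat(sprintf("HotspotSet (%s, %s): %d cells (%.2f%% of %d valid; cutoff %.4g)\n",
              x$metric, x$scenario, nrow(x$cells),
              100 * nrow(x$cells) / x$nValid, x$nValid, x$cutoff))
  invisible(x)
}

#' Two-sample Watson U-squared statistic for circular data
#'
#' @param a,b angles in radians.
#' @return the U-squared statistic.
#' @export
watsonU2 <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ang <- c(a, b) %% (2 * pi)
  ord <- order(ang)
  grp <- c(rep(1, n1), rep(2, n2))[ord]
  f1 <- cumsum(grp == 1) / n1
  f2 <- cumsum(grp == 2) / n2
  d <- f1 - f2
  (n1 * n2 / N^2) * sum((d - mean(d))^2)
}

#' Test altitudinal and directional shifts between two hotspot sets
#'
#' Altitudinal shift: Kruskal-Wallis test on cell elevations (current vs
#' future). Directional shift: two-sample Watson U-squared on the bearings
#' from the current-period centroid to each hotspot cell, with a
#' permutation p-value (`nPerm` label shuffles). Centroids (mean lon/lat)
#' and mean elevations are always reported; the tests are skipped (NA) when
#' a group has fewer than 3 cells.
#'
#' @param current,future `HotspotSet`s (see [l1Hotspots()]).
#' @param nPerm permutations for the Watson p-value (default 999).
#' @param seed integer seed.
#' @return list of class `ShiftTestResult`: `kwH`, `kwDf`, `kwP`,
#'   `watsonU2`, `watsonP`, `centroidCurrent`, `centroidFuture`,
#'   `meanAltCurrent`, `meanAltFuture`.
#' @export
shiftTests <- function(current, future, nPerm = 999, seed = 1) {
  stopifnot(nrow(current$cells) >= 1, nrow(future$cells) >= 1)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  cc <- current$cells; fc <- future$cells
  centC <- c(lon = mean(cc$lon), lat = mean(cc$lat))
  centF <- c(lon = mean(fc$lon), lat = mean(fc$lat))
  altC <- mean(cc$elevation); altF <- mean(fc$elevation)

  kwH <- kwDf <- kwP <- u2 <- u2p <- NA_real_
  if (nrow(cc) >= 3 && nrow(fc) >= 3) {
    elev <- c(cc$elevation, fc$elevation)
    grp <- factor(c(rep("current", nrow(cc)), rep("future", nrow(fc))))
    if (all(!is.na(elev))) {
      if (diff(range(elev)) < 1e-24) {   # identical constants: no shift
        kwH <- 0; kwDf <- 1; kwP <- 1
      } else {
        kw <- kruskal.test(elev, grp)
        kwH <- unname(kw$statistic); kwDf <- unname(kw$parameter)
        kwP <- kw$p.value
      }
    }

    bearing <- function(df) atan2(df$y - mean(cc$y), df$x - mean(cc$x))
    aC <- bearing(cc); aF <- bearing(fc)
    # drop zero-length bearings (a cell exactly at the centroid)
    okC <- !(abs(cc$x - mean(cc$x)) < 1e-9 & abs(cc$y - mean(cc$y)) < 1e-9)
    aC <- aC[okC]
    if (length(aC) >= 3) {
      u2 <- watsonU2(aC, aF)
      all <- c(aC, aF); n1 <- length(aC)
      perm <- vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(length(all), n1)
        watsonU2(all[idx], all[-idx])
      }, 1)
      u2p <- (1 + sum(perm >= u2)) / (nPerm + 1)
    }
  }
  structure(list(kwH = kwH, kwDf = kwDf, kwP = kwP, watsonU2 = u2,
                 watsonP = u2p, centroidCurrent = centC,
                 centroidFuture = centF, meanAltCurrent = altC,
                 meanAltFuture = altF),
            class = "ShiftTestResult")
}

#' @export
print.ShiftTestResult <- function(x, ...) {
  cat(sprintf("ShiftTestResult: KW H = %.2f (df %s, p %.3g); Watson U2 = %.4g (p %.3g)\n",
              x$kwH, format(x$kwDf), x$kwP, x$watsonU2, x$watsonP))
  cat(sprintf("  centroid %.3f,%.3f -> %.3f,%.3f; mean alt %.0f -> %.0f m\n",
              x$centroidCurrent["lon"], x$centroidCurrent["lat"],
              x$centroidFuture["lon"], x$centroidFuture["lat"],
              x$meanAltCurrent, x$meanAltFuture))
  invisible(x)
}

#' Pooled multi-group Kruskal-Wallis over several hotspot sets
#'
#' @param hotspotList named list of `HotspotSet`s (e.g. one per time-slice).
#' @return `kruskal.test` result on elevations across all groups.
#' @export
hotspotShiftKW <- function(hotspotList) {
  stopifnot(length(hotspotList) >= 2)
  elev <- unlist(lapply(hotspotList, function(h) h$cells$elevation))
  grp <- factor(rep(names(hotspotList),
                    vapply(hotspotList, function(h) nrow(h$cells), 1L)))
  kruskal.test(elev, grp)
}

#' Contrast species richness across human-modification classes
#'
#' Cells are classified by the human-modification index into
#' low / moderate / high / very-high using `breaks`; per-class SR samples
#' are compared with a Kruskal-Wallis test (skipped when fewer than two
#' non-empty classes).
#'
#' @param div a `DiversityMaps` (its `sr` layer is used) or a
#'   [RasterGrid-class] of SR values.
#' @param ghm human-modification [RasterGrid-class] in `[0, 1]`, aligned.
#' @param breaks strictly increasing class breaks in (0, 1).
#' @return list of class `HumanModContrast`: `classValues` (named list of
#'   SR samples), `classMedians`, `kwH`, `kwDf`, `kwP`, `classes`.
#' @export
humanModContrast <- function(div, ghm, breaks = c(0.1, 0.4, 0.7)) {
  sr <- if (inherits(div, "DiversityMaps")) div$sr else div
  checkAligned(sr, ghm)
  stopifnot(all(diff(breaks) > 0), all(breaks > 0 & breaks < 1))
  labels <- c("low", "moderate", "high", "very-high")[seq_len(length(breaks) + 1)]
  ok <- !is.na(sr@values) & !is.na(ghm@values)
  cls <- cut(ghm@values[ok], breaks = c(-Inf, breaks, Inf), labels = labels)
  vals <- split(sr@values[ok], cls)
  nonEmpty <- vals[vapply(vals, length, 1L) > 0]
  kwH <- kwDf <- kwP <- NA_real_
  if (length(nonEmpty) >= 2 &&
      diff(range(unlist(nonEmpty))) > 1e-24) {
    kw <- kruskal.test(unlist(nonEmpty),
                       factor(rep(names(nonEmpty),
                                  vapply(nonEmpty, length, 1L))))
    kwH <- unname(kw$statistic); kwDf <- unname(kw$parameter)
    kwP <- kw$p.value
  }
  structure(list(classValues = vals,
                 classMedians = vapply(vals, function(v)
                   if (length(v)) median(v) else NA_real_, 1),
                 kwH = kwH, kwDf = kwDf, kwP = kwP, classes = labels),
            class = "HumanModContrast")
}

#' @export
print.HumanModContrast <- function(x, ...) {
  cat("HumanModContrast: class medians",
      paste(sprintf("%s = %.3g", names(x$classMedians), x$classMedians),
            collapse = ", "),
      sprintf("; KW H = %.2f, p = %.3g\n", x$kwH, x$kwP))
  invisible(x)
}

#' Write a hotspot set as GeoJSON points plus CSV
#'
#' @param hs a `HotspotSet`.
#' @param file base path (writes `<file>.geojson` and `<file>.csv`).
#' @export
writeHotspots <- function(hs, file) {
  write.csv(hs$cells, paste0(file, ".csv"), row.names = FALSE)
  feats <- lapply(seq_len(nrow(hs$cells)), function(i)
    list(type = "Feature",
         properties = list(value = hs$cells$value[i],
                           elevation = hs$cells$elevation[i]),
         geometry = list(type = "Point",
                         coordinates = c(hs$cells$lon[i], hs$cells$lat[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       paste0(file, ".geojson"), auto_unbox = TRUE,
                       digits = 10)
  invisible(file)
}
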