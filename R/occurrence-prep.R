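# great-circle distances in km on the authalic sphere
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

# full pairwise great-circle distance matrix for a set of points
pairwiseKm <- function(lon, lat) {
  n <- length(lon)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversineKm(lon[i], lat[i], lon[j], lat[j])
  }
  d
}

#' Remove duplicate records (one per species and grid cell)
#'
#' Records falling off the grid or on sea cells are dropped with a warning.
#' The first record per (species, cell) is retained.
#'
#' @param occ occurrence data.frame (`species`, `lon`, `lat`).
#' @param grid land [RasterGrid-class] (nodata = sea).
#' @return deduplicated data.frame, `stage = "deduped"`.
#' @export
dedupeOccurrences <- function(occ, grid) {
  idx <- cellFromLonLat(grid, occ$lon, occ$lat)
  onGrid <- !is.na(idx$cell)
  onLand <- onGrid & !is.na(grid@values[cbind(idx$row, idx$col)])
  if (any(!onLand))
    warning(sprintf("%d record(s) off-grid or on sea dropped", sum(!onLand)))
  occ <- occ[onLand, , drop = FALSE]
  cell <- idx$cell[onLand]
  keep <- !duplicated(paste(occ$species, cell))
  out <- occ[keep, , drop = FALSE]
  out$stage <- "deduped"
  rownames(out) <- NULL
  out
}

# greedy thinning of one species: random-order insertion, best of nRepeats
thinOne <- function(lon, lat, thinDist, nRepeats) {
  n <- length(lon)
  if (n <= 1) return(seq_len(n))
  d <- pairwiseKm(lon, lat)
  best <- integer(0)
  for (r in seq_len(nRepeats)) {
    ord <- sample.int(n)
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(d[i, kept] >= thinDist)) kept <- c(kept, i)
    if (length(kept) > length(best)) best <- kept
  }
  sort(best)
}

#' Spatially thin occurrence records
#'
#' Per species, retains a large subset with all pairwise great-circle
#' distances `>= thinDist`, found by randomized greedy insertion repeated
#' `nRepeats` times (best repeat kept). Idempotent on its own output.
#'
#' @param occ occurrence data.frame.
#' @param thinDist minimum pairwise distance, km.
#' @param nRepeats number of random restarts (default 20).
#' @param seed integer seed.
#' @return thinned data.frame, `stage = "thinned"`.
#' @export
thinOccurrences <- function(occ, thinDist, nRepeats = 20, seed = 1) {
  stopifnot(thinDist > 0)
  force(occ)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  keepRows <- integer(0)
  for (sp in unique(occ$species)) {
    rows <- which(occ$species == sp)
    kept <- thinOne(occ$lon[rows], occ$lat[rows], thinDist, nRepeats)
    keepRows <- c(keepRows, rows[kept])
  }
  out <- occ[sort(keepRows), , drop = FALSE]
  out$stage <- "thinned"
  rownames(out) <- NULL
  out
}

#' Drop species with too few records
#'
#' @param occ occurrence data.frame (normally thinned).
#' @param minRecords minimum records per species (default 3).
#' @return list with `occurrences` (filtered data.frame) and
#'   `droppedSpecies` (character vector).
#' @export
filterMinRecords <- function(occ, minRecords = 3) {
  if (!nrow(occ))
    return(list(occurrences = occ, droppedSpecies = character(0)))
  counts <- table(occ$species)
  dropped <- names(counts[counts < minRecords])
  out <- occ[!occ$species %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  list(occurrences = out, droppedSpecies = dropped)
}

#' Fit an accessibility sampling-bias model
#'
#' Per-cell record counts (all species pooled) are modelled as Poisson with
#' rate `q exp(-sum_f w_f d_f)` where `d_f` are distance rasters (km) to
#' accessibility features (settlements, ...). `q` is profiled out in closed
#' form; the decay rates `w_f >= 0` are found by bounded numerical
#' optimization of the profile likelihood.
#'
#' @param occ occurrence data.frame (records on land).
#' @param distanceStack [LayerStack-class] of distance rasters (km).
#' @param grid land [RasterGrid-class] defining the cells.
#' @return list of class `BiasModel`: `q` (records/cell at distance 0), `w`
#'   (named per-factor decay, per km), `loglik`, `rate` (expected
#'   sampling-rate raster), `nRecords`.
#' @export
fitBiasModel <- function(occ, distanceStack, grid) {
  stopifnot(length(distanceStack) >= 1)
  cells <- validCells(grid)
  idx <- cellFromLonLat(grid, occ$lon, occ$lat)
  counts <- tabulate(match(idx$cell, cells), nbins = length(cells))
  D <- stackValues(distanceStack, cells)
  C <- sum(counts)
  if (C == 0) stop("no records on land; cannot fit bias model")
  nF <- ncol(D)

  profile <- function(w) {
    eta <- as.vector(D %*% w)
    s <- exp(-eta)
    q <- C / sum(s)
    sum(counts * (log(q) - eta)) - C   # log-lik up to -sum(log c_i!)
  }
  opt <- optim(rep(0.01, nF), function(w) -profile(w), method = "L-BFGS-B",
               lower = rep(0, nF), upper = rep(20, nF))
  if (opt$convergence != 0)
    stop("bias-model optimizer failed to converge: ", opt$message)
  w <- setNames(opt$par, colnames(D))
  eta <- as.vector(D %*% w)
  q <- C / sum(exp(-eta))
  rate <- sameGrid(grid, NA_real_)
  rate@values[cells] <- q * exp(-eta)
  structure(list(q = q, w = w, loglik = -opt$value, rate = rate,
                 nRecords = C), class = "BiasModel")
}

#' @export
print.BiasModel <- function(x, ...) {
  cat(sprintf("BiasModel: q = %.4g records/cell; decay per km: %s (loglik %.2f)\n",
              x$q, paste(sprintf("%s = %.3g", names(x$w), x$w), collapse = ", "),
              x$loglik))
  invisible(x)
}

#' Serialize a bias model to JSON (without the rate raster)
#'
#' @param model a `BiasModel`.
#' @param file output path.
#' @export
writeBiasModel <- function(model, file) {
  jsonlite::write_json(list(q = model$q, w = as.list(model$w),
                            loglik = model$loglik, nRecords = model$nRecords),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
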