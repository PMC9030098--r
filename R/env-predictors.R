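# days per month (non-leap), used for PET and degree-day accumulation
.DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# climate values as cells x 12 matrices over all grid cells
climMatrices <- function(clim) {
  list(tmin = vapply(clim@tmin, function(g) as.vector(g@values),
                     numeric(length(clim@tmin[[1]]@values))),
       tmax = vapply(clim@tmax, function(g) as.vector(g@values),
                     numeric(length(clim@tmax[[1]]@values))),
       prec = vapply(clim@prec, function(g) as.vector(g@values),
                     numeric(length(clim@prec[[1]]@values))))
}

# all 12 wrap-around 3-month window sums of a cells x 12 matrix
quarterSums <- function(m) {
  idx <- cbind(1:12, c(2:12, 1), c(3:12, 1, 2))
  out <- matrix(NA_real_, nrow(m), 12)
  for (q in 1:12) out[, q] <- m[, idx[q, 1]] + m[, idx[q, 2]] + m[, idx[q, 3]]
  out
}

# row-wise selection: value of `m`'s quarter chosen by which.max/min of `by`;
# ties resolved to the lowest starting month (max.col over -index penalty)
pickQuarter <- function(m, by, which = c("max", "min")) {
  which <- match.arg(which)
  sel <- if (which == "max") max.col(by, ties.method = "first")
         else max.col(-by, ties.method = "first")
  m[cbind(seq_len(nrow(m)), sel)]
}

#' Derive the 19 standard bioclimatic variables
#'
#' Monthly mean temperature is `(tmin + tmax)/2`; quarters are all 12
#' wrap-around consecutive 3-month windows, with warmest/coldest picked by
#' mean-temperature sum and wettest/driest by precipitation sum (ties go to
#' the lowest starting month). `bio4` is 100 x the (sample) SD of monthly
#' means; `bio15` is the precipitation coefficient of variation
#' `100 x sd / (1 + bio12/12)`.
#'
#' @param clim a [ClimateSet-class] with all 12 months present.
#' @return A [LayerStack-class] with layers `bio1` .. `bio19`.
#' @export
deriveBioclim <- function(clim) {
  for (s in c("tmin", "tmax", "prec")) {
    l <- slot(clim, s)
    missing <- which(vapply(l, function(g) all(is.na(g@values)), TRUE))
    if (length(l) != 12)
      stop(sprintf("%s must have 12 months", s))
  }
  cm <- climMatrices(clim)
  tavg <- (cm$tmin + cm$tmax) / 2
  prec <- cm$prec
  template <- clim@tmin[[1]]

  tq <- quarterSums(tavg)   # quarter tavg sums
  pq <- quarterSums(prec)   # quarter prec sums

  bio <- list()
  bio$bio1 <- rowMeans(tavg)
  bio$bio2 <- rowMeans(cm$tmax - cm$tmin)
  bio$bio5 <- apply(cm$tmax, 1, max)
  bio$bio6 <- apply(cm$tmin, 1, min)
  bio$bio7 <- bio$bio5 - bio$bio6
  bio$bio3 <- ifelse(bio$bio7 == 0, NA, 100 * bio$bio2 / bio$bio7)
  bio$bio4 <- 100 * apply(tavg, 1, sd)
  bio$bio8 <- pickQuarter(tq, pq, "max") / 3     # mean temp, wettest quarter
  bio$bio9 <- pickQuarter(tq, pq, "min") / 3     # driest
  bio$bio10 <- pickQuarter(tq, tq, "max") / 3    # warmest
  bio$bio11 <- pickQuarter(tq, tq, "min") / 3    # coldest
  bio$bio12 <- rowSums(prec)
  bio$bio13 <- apply(prec, 1, max)
  bio$bio14 <- apply(prec, 1, min)
  bio$bio15 <- 100 * apply(prec, 1, sd) / (1 + bio$bio12 / 12)
  bio$bio16 <- pickQuarter(pq, pq, "max")
  bio$bio17 <- pickQuarter(pq, pq, "min")
  bio$bio18 <- pickQuarter(pq, tq, "max")        # prec of warmest quarter
  bio$bio19 <- pickQuarter(pq, tq, "min")        # prec of coldest quarter
  bio <- bio[paste0("bio", 1:19)]

  nas <- is.na(tavg[, 1])
  layers <- lapply(bio, function(v) { v[nas] <- NA; sameGrid(template, v) })
  layerStack(layers,
             setNames(rep("derived from monthly tmin/tmax/prec", 19),
                      names(layers)))
}

# FAO-56 extraterrestrial radiation, MJ m-2 day-1, for latitude (deg) and month
extraterrestrialRadiation <- function(latDeg, month) {
  J <- cumsum(.DAYS_IN_MONTH) - .DAYS_IN_MONTH / 2   # mid-month day of year
  phi <- latDeg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J[month] / 365)
  delta <- 0.409 * sin(2 * pi * J[month] / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Derive PET-family and moisture variables from monthly climate
#'
#' Monthly potential evapotranspiration follows the Hargreaves formulation
#' `PET = 0.0023 Ra (Tmean + 17.8) sqrt(Tmax - Tmin)` (mm/day, floored at 0),
#' with extraterrestrial radiation `Ra` from latitude and month. Derived
#' layers: quarter PET sums (quarters chosen exactly as in
#' [deriveBioclim()]), annual PET, the Thornthwaite aridity index
#' `100 x annual water deficit / annual PET` (maximal when precipitation is
#' zero), the Willmott-Feddema climatic moisture index in `[-1, 1]`,
#' continentality (warmest minus coldest monthly mean), and growing
#' degree-day sums above 0 and 5 degC.
#'
#' @param clim a [ClimateSet-class].
#' @param latitude optional latitude [RasterGrid-class] aligned to the
#'   climate grids (default: derived from the grid geometry).
#' @return A [LayerStack-class].
#' @export
deriveEnvirem <- function(clim, latitude = NULL) {
  template <- clim@tmin[[1]]
  if (is.null(latitude)) latitude <- latitudeGrid(template)
  checkAligned(template, latitude)
  lat <- as.vector(latitude@values)
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  cm <- climMatrices(clim)
  tavg <- (cm$tmin + cm$tmax) / 2
  trange <- cm$tmax - cm$tmin

  pet <- matrix(NA_real_, nrow(tavg), 12)
  for (m in 1:12) {
    ra <- extraterrestrialRadiation(lat, m)      # MJ m-2 day-1
    raMm <- 0.408 * ra                           # mm/day equivalent
    petDay <- 0.0023 * raMm * (tavg[, m] + 17.8) * sqrt(pmax(trange[, m], 0))
    pet[, m] <- pmax(petDay, 0) * .DAYS_IN_MONTH[m]
  }

  tq <- quarterSums(tavg)
  pq <- quarterSums(cm$prec)
  petq <- quarterSums(pet)

  annualPET <- rowSums(pet)
  deficit <- rowSums(pmax(pet - cm$prec, 0))
  aridity <- ifelse(annualPET > 0, 100 * deficit / annualPET, 0)
  p <- rowSums(cm$prec)
  cmi <- ifelse(p >= annualPET,
                1 - ifelse(p > 0, annualPET / p, 1),
                p / pmax(annualPET, 1e-12) - 1)
  gdd <- function(base) rowSums(pmax(tavg - base, 0) *
                                  matrix(.DAYS_IN_MONTH, nrow(tavg), 12,
                                         byrow = TRUE))
  out <- list(
    annualPET = annualPET,
    PETColdestQuarter = pickQuarter(petq, tq, "min"),
    PETWarmestQuarter = pickQuarter(petq, tq, "max"),
    PETWettestQuarter = pickQuarter(petq, pq, "max"),
    PETDriestQuarter = pickQuarter(petq, pq, "min"),
    aridityIndexThornthwaite = aridity,
    climaticMoistureIndex = cmi,
    continentality = apply(tavg, 1, max) - apply(tavg, 1, min),
    growingDegDays0 = gdd(0),
    growingDegDays5 = gdd(5))
  nas <- is.na(tavg[, 1])
  layers <- lapply(out, function(v) { v[nas] <- NA; sameGrid(template, v) })
  layerStack(layers, setNames(rep("Hargreaves PET family", length(layers)),
                              names(layers)))
}

#' Derive topographic variables from a DEM
#'
#' Slope and aspect by Horn's 3x3 finite differences (aspect in compass
#' degrees); topographic position index (elevation minus 8-neighbour mean);
#' terrain ruggedness index (mean absolute 8-neighbour difference); and the
#' McCune-Keon heat load index from folded aspect
#' `A' = |180 - |aspect - 225||`:
#' `HLI = exp(-1.467 + 1.582 cos(lat) cos(s) - 1.500 cos(A') sin(s) cos(lat)
#'  - 0.262 sin(lat) sin(s) + 0.607 sin(A') sin(s))`.
#' Cells on the grid edge or with any nodata neighbour are nodata.
#'
#' @param dem elevation [RasterGrid-class] (m).
#' @param latitude optional latitude grid (default from geometry).
#' @return A [LayerStack-class] with `slope` (deg), `aspect` (deg), `tpi`
#'   (m), `tri` (m) and `hli`.
#' @export
deriveTopographic <- function(dem, latitude = NULL) {
  v <- dem@values
  if (all(is.na(v))) stop("DEM has no valid cells")
  if (is.null(latitude)) latitude <- latitudeGrid(dem)
  nr <- nrow(v); nc <- ncol(v)
  cs <- dem@cellKm * 1000   # metres

  # 8 shifted copies; NA-edged
  sh <- function(di, dj) {
    out <- matrix(NA_real_, nr, nc)
    ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
    okR <- ri >= 1 & ri <= nr; okC <- cj >= 1 & cj <= nc
    out[okR, okC] <- v[ri[okR], cj[okC]]
    out
  }
  z1 <- sh(-1, -1); z2 <- sh(-1, 0); z3 <- sh(-1, 1)   # NW N NE
  z4 <- sh(0, -1);                    z6 <- sh(0, 1)    # W     E
  z7 <- sh(1, -1);  z8 <- sh(1, 0);  z9 <- sh(1, 1)     # SW S SE

  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cs)
  dzdy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * cs)  # north positive
  slopeRad <- atan(sqrt(dzdx^2 + dzdy^2))
  # downslope-facing direction, compass degrees clockwise from north
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  flat <- sqrt(dzdx^2 + dzdy^2) < 1e-12
  aspect[flat] <- 0

  nbrs <- list(z1, z2, z3, z4, z6, z7, z8, z9)
  nbrSum <- Reduce(`+`, nbrs)
  tpi <- v - nbrSum / 8
  tri <- Reduce(`+`, lapply(nbrs, function(z) abs(v - z))) / 8

  latRad <- latitude@values * pi / 180
  folded <- abs(180 - abs(aspect - 225)) * pi / 180
  hli <- exp(-1.467 + 1.582 * cos(latRad) * cos(slopeRad) -
             1.500 * cos(folded) * sin(slopeRad) * cos(latRad) -
             0.262 * sin(latRad) * sin(slopeRad) +
             0.607 * sin(folded) * sin(slopeRad))

  bad <- is.na(v) | Reduce(`|`, lapply(nbrs, is.na))
  mk <- function(x) { x[bad] <- NA; sameGrid(dem, x) }
  layerStack(list(slope = mk(slopeRad * 180 / pi), aspect = mk(aspect),
                  tpi = mk(tpi), tri = mk(tri), hli = mk(hli)),
             c(slope = "Horn 3x3", aspect = "Horn 3x3",
               tpi = "elev - 8-neighbour mean",
               tri = "mean |elev - neighbour|", hli = "McCune-Keon"))
}

#' Combine stacks
#'
#' @param ... [LayerStack-class] objects with unique layer names.
#' @return A single [LayerStack-class].
#' @export
combineStacks <- function(...) {
  stacks <- list(...)
  layers <- do.call(c, lapply(stacks, function(s) s@layers))
  prov <- do.call(c, lapply(stacks, function(s) s@provenance))
  layerStack(layers, prov)
}

#' Filter a predictor stack for collinearity
#'
#' Statistics are computed on a seeded random sample of cells valid in every
#' layer. Zero-variance layers are dropped first. Then, while any pair of
#' retained layers has `|Spearman rho| >= rhoMax`, the member of the worst
#' pair with the higher mean absolute correlation against the others is
#' dropped. Finally, while any retained layer has variance inflation factor
#' `>= vifMax` (computed as `1/(1 - R^2)` from a linear regression on the
#' other retained layers), the highest-VIF layer is dropped. Layers listed in
#' `keep` are never dropped (used to protect variables of known ecological
#' relevance, e.g. the true niche axes in virtual-species experiments).
#'
#' @param stack a [LayerStack-class] with at least 2 layers.
#' @param samples number of cells sampled for the statistics.
#' @param rhoMax pairwise Spearman threshold (default 0.7).
#' @param vifMax VIF threshold (default 10).
#' @param keep layer names never dropped.
#' @param seed integer seed for the cell sample.
#' @return A `CollinearityReport` list: `retained`, `dropped` (data.frame
#'   `layer`, `reason`, `value`), `rhoMax`, `vifMax`, `nSamples`.
#' @export
filterCollinear <- function(stack, samples = 10000, rhoMax = 0.7,
                            vifMax = 10, keep = character(0), seed = 1) {
  stopifnot(length(stack) >= 2)
  oldSeed <- pushSeed(seed)
  on.exit(restoreRNG(oldSeed), add = TRUE)
  ok <- Reduce(`&`, lapply(stack@layers, function(g) !is.na(g@values)))
  cells <- which(ok)
  if (length(cells) < 2) stop("not enough jointly valid cells")
  if (length(cells) > samples) cells <- sort(sample(cells, samples))
  X <- stackValues(stack, cells)
  nms <- colnames(X)
  dropped <- data.frame(layer = character(0), reason = character(0),
                        value = numeric(0), stringsAsFactors = FALSE)
  drop1 <- function(nm, reason, value) {
    dropped[nrow(dropped) + 1, ] <<- list(nm, reason, value)
    nms <<- setdiff(nms, nm)
  }
  # zero-variance pass
  for (nm in nms[vapply(nms, function(n) var(X[, n]) < 1e-24, TRUE)])
    drop1(nm, "zero variance", 0)

  # Spearman pass
  repeat {
    if (length(nms) < 2) break
    rho <- abs(cor(X[, nms, drop = FALSE], method = "spearman"))
    diag(rho) <- 0
    worst <- which(rho == max(rho), arr.ind = TRUE)[1, ]
    if (rho[worst[1], worst[2]] < rhoMax) break
    pair <- nms[c(worst[1], worst[2])]
    cand <- setdiff(pair, keep)
    if (!length(cand)) { # both protected; cannot resolve this pair
      warning(sprintf("protected layers '%s' and '%s' exceed rhoMax; both kept",
                      pair[1], pair[2]))
      rhoP <- rho; rhoP[pair, pair] <- 0
      if (max(rhoP) < rhoMax) break
      # mask the protected pair and continue with the next-worst pair
      nxt <- which(rhoP == max(rhoP), arr.ind = TRUE)[1, ]
      pair <- nms[c(nxt[1], nxt[2])]
      cand <- setdiff(pair, keep)
      if (!length(cand)) break
    }
    meanAbs <- colMeans(rho[, cand, drop = FALSE])
    victim <- cand[which.max(meanAbs)]
    other <- setdiff(pair, victim)[1]
    drop1(victim, sprintf("|rho| with %s", other),
          max(abs(cor(X[, victim], X[, setdiff(pair, victim)],
                      method = "spearman"))))
  }

  # VIF pass
  vifOf <- function(nm, others) {
    if (!length(others)) return(1)
    fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), X[, nm])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, nm] - mean(X[, nm]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(nms) < 2) break
    vifs <- vapply(nms, function(n) vifOf(n, setdiff(nms, n)), 1)
    cand <- setdiff(nms, keep)
    if (!length(cand) || max(vifs[cand]) < vifMax) break
    # ties (e.g. several exactly collinear layers): drop the layer with the
    # highest mean absolute rank correlation against the rest
    top <- cand[vifs[cand] >= max(vifs[cand]) * (1 - 1e-9)]
    if (length(top) > 1) {
      rho <- abs(cor(X[, nms, drop = FALSE], method = "spearman"))
      diag(rho) <- 0
      victim <- top[which.max(colMeans(rho)[top])]
    } else victim <- top
    drop1(victim, "VIF", unname(vifs[victim]))
  }

  structure(list(retained = nms, dropped = dropped, rhoMax = rhoMax,
                 vifMax = vifMax, nSamples = length(cells)),
            class = "CollinearityReport")
}

#' @export
print.CollinearityReport <- function(x, ...) {
  cat(sprintf("CollinearityReport: %d retained, %d dropped (rho < %.2f, VIF < %.1f)\n",
              length(x$retained), nrow(x$dropped), x$rhoMax, x$vifMax))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (%s = %.3g)\n", x$dropped$layer[i],
                  x$dropped$reason[i], x$dropped$value[i]))
  invisible(x)
}

#' Write a layer stack as ASCII grids plus a JSON manifest
#'
#' @param stack a [LayerStack-class].
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
writeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in layerNames(stack)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(getLayer(stack, nm), f)
    files[nm] <- basename(f)
  }
  manifest <- file.path(dir, "stack.json")
  jsonlite::write_json(
    list(layers = as.list(files),
         provenance = as.list(stack@provenance)),
    manifest, auto_unbox = TRUE)
  manifest
}

#' Read a layer stack written by [writeStack()]
#'
#' @param dir directory holding `stack.json`.
#' @return A [LayerStack-class].
#' @export
readStack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "stack.json"))
  layers <- lapply(man$layers, function(f) readAsciiGrid(file.path(dir, f)))
  layerStack(layers, unlist(man$provenance))
}
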