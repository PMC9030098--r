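# Earth radii used for the degree <-> km linear map (authalic sphere).
.KM_PER_DEG_LAT <- 111.195

# Seed the RNG for a deterministic operation while leaving the caller's
# random stream untouched. Usage:  on.exit(restoreRNG(pushSeed(seed)))
pushSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row) or a single value
#'   recycled to `dim`.
#' @param cellKm cell side in km.
#' @param dim integer `(nrow, ncol)`, required when `values` is not a matrix.
#' @param xllKm,yllKm planar coordinates of the lower-left corner (km).
#' @param refLon,refLat lon/lat (degrees) of the lower-left corner.
#' @return A [RasterGrid-class].
#' @export
rasterGrid <- function(values, cellKm = 1, dim = NULL, xllKm = 0, yllKm = 0,
                       refLon = 25, refLat = 37) {
  if (!is.matrix(values)) {
    stopifnot(!is.null(dim))
    values <- matrix(as.numeric(values), nrow = dim[1], ncol = dim[2])
  }
  new("RasterGrid", values = values, cellKm = cellKm, xllKm = xllKm,
      yllKm = yllKm, refLon = refLon, refLat = refLat)
}

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' Raster cell values
#' @param x a [RasterGrid-class].
#' @return the value matrix (row 1 = north).
#' @rdname gridValues
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))
#' @rdname gridValues
#' @param value replacement matrix.
#' @export
setMethod("gridValues<-", "RasterGrid", function(x, value) {
  stopifnot(identical(dim(value), dim(x@values)))
  x@values <- value
  validObject(x)
  x
})

#' @export
setGeneric("cellKm", function(x) standardGeneric("cellKm"))
#' Cell size in km
#' @param x a [RasterGrid-class] (or object carrying one).
#' @rdname cellKm
#' @export
setMethod("cellKm", "RasterGrid", function(x) x@cellKm)

setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells of %.3g km\n", nrow(v), ncol(v),
              object@cellKm))
  cat(sprintf("  origin (lower-left): lon %.4f, lat %.4f\n", object@refLon,
              object@refLat))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%.4g, %.4g], %d valid of %d cells\n",
                min(v[ok]), max(v[ok]), sum(ok), length(v)))
  else cat("  all cells nodata\n")
  invisible(object)
})

# --- geometry helpers -------------------------------------------------------

#' Planar x/y (km) of every cell centre
#'
#' @param grid a [RasterGrid-class].
#' @return list with matrices `x` and `y` of cell-centre coordinates (km),
#'   same shape as the grid.
#' @export
cellCentersXY <- function(grid) {
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  xs <- grid@xllKm + (seq_len(nc) - 0.5) * grid@cellKm
  ys <- grid@yllKm + (nr - seq_len(nr) + 0.5) * grid@cellKm  # row 1 = top
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Convert planar km coordinates to lon/lat degrees
#'
#' @param grid reference [RasterGrid-class] providing the origin.
#' @param x,y planar coordinates in km.
#' @return data.frame with `lon`, `lat`.
#' @export
xyToLonLat <- function(grid, x, y) {
  lat <- grid@refLat + (y - grid@yllKm) / .KM_PER_DEG_LAT
  lon <- grid@refLon + (x - grid@xllKm) /
    (.KM_PER_DEG_LAT * cos(grid@refLat * pi / 180))
  data.frame(lon = lon, lat = lat)
}

#' Convert lon/lat degrees to planar km coordinates
#'
#' @inheritParams xyToLonLat
#' @param lon,lat coordinates in degrees.
#' @return data.frame with `x`, `y` in km.
#' @export
lonLatToXY <- function(grid, lon, lat) {
  y <- grid@yllKm + (lat - grid@refLat) * .KM_PER_DEG_LAT
  x <- grid@xllKm + (lon - grid@refLon) *
    .KM_PER_DEG_LAT * cos(grid@refLat * pi / 180)
  data.frame(x = x, y = y)
}

#' Latitude of every cell centre
#'
#' @param grid a [RasterGrid-class].
#' @return a [RasterGrid-class] of latitudes (degrees).
#' @export
latitudeGrid <- function(grid) {
  cc <- cellCentersXY(grid)
  ll <- xyToLonLat(grid, as.vector(cc$x), as.vector(cc$y))
  out <- grid
  out@values <- matrix(ll$lat, nrow(grid@values), ncol(grid@values))
  out
}

#' Cell index (matrix row/col and linear index) of lon/lat points
#'
#' @param grid a [RasterGrid-class].
#' @param lon,lat point coordinates (degrees).
#' @return data.frame with `row`, `col`, `cell` (linear, column-major);
#'   `NA` for points off the grid.
#' @export
cellFromLonLat <- function(grid, lon, lat) {
  xy <- lonLatToXY(grid, lon, lat)
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  col <- floor((xy$x - grid@xllKm) / grid@cellKm) + 1
  rowFromBottom <- floor((xy$y - grid@yllKm) / grid@cellKm) + 1
  row <- nr - rowFromBottom + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(col) | !is.finite(row)
  row[bad] <- NA; col[bad] <- NA
  data.frame(row = row, col = col, cell = (col - 1) * nr + row)
}

#' Lon/lat of cell centres for linear cell indices
#'
#' @param grid a [RasterGrid-class].
#' @param cell linear (column-major) cell indices.
#' @return data.frame with `x`, `y` (km) and `lon`, `lat` (degrees).
#' @export
lonLatFromCell <- function(grid, cell) {
  nr <- nrow(grid@values)
  row <- ((cell - 1) %% nr) + 1
  col <- ((cell - 1) %/% nr) + 1
  x <- grid@xllKm + (col - 0.5) * grid@cellKm
  y <- grid@yllKm + (nr - row + 0.5) * grid@cellKm
  cbind(data.frame(x = x, y = y), xyToLonLat(grid, x, y))
}

#' Indices of valid (non-nodata) cells
#'
#' @param grid a [RasterGrid-class].
#' @return integer vector of linear (column-major) cell indices.
#' @export
validCells <- function(grid) which(!is.na(grid@values))

# internal: new grid with same geometry, given values (vector or matrix)
sameGrid <- function(template, values) {
  g <- template
  if (!is.matrix(values))
    values <- matrix(values, nrow(template@values), ncol(template@values))
  g@values <- values
  g
}

# internal: assert aligned geometry
checkAligned <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)) ||
      abs(a@cellKm - b@cellKm) > 1e-9)
    stop("raster grids are not aligned")
  invisible(TRUE)
}

#' Planar distance (km) from every cell centre to the nearest of a point set
#'
#' @param grid a [RasterGrid-class].
#' @param points matrix/data.frame with planar `x`, `y` columns in km.
#' @return a [RasterGrid-class] of distances; nodata where `grid` is nodata.
#' @export
distanceToPoints <- function(grid, points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  cc <- cellCentersXY(grid)
  x <- as.vector(cc$x); y <- as.vector(cc$y)
  d2 <- matrix(Inf, length(x), 1)
  dmin <- rep(Inf, length(x))
  for (k in seq_len(nrow(points))) {
    dk <- (x - points[k, 1])^2 + (y - points[k, 2])^2
    dmin <- pmin(dmin, dk)
  }
  out <- sameGrid(grid, sqrt(dmin))
  out@values[is.na(grid@values)] <- NA
  out
}

# --- LayerStack -------------------------------------------------------------

#' Construct a LayerStack
#'
#' @param layers named list of [RasterGrid-class] objects.
#' @param provenance optional named character vector of derivation notes.
#' @return A [LayerStack-class].
#' @export
layerStack <- function(layers, provenance = character(0)) {
  if (length(provenance) == 0 && length(layers))
    provenance <- setNames(rep("", length(layers)), names(layers))
  new("LayerStack", layers = layers, provenance = provenance)
}

#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' Names of the layers in a stack
#' @param x a [LayerStack-class].
#' @rdname layerNames
#' @export
setMethod("layerNames", "LayerStack", function(x) names(x@layers))

#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' Extract one layer
#' @param x a [LayerStack-class].
#' @param name layer name.
#' @rdname getLayer
#' @export
setMethod("getLayer", "LayerStack", function(x, name) {
  if (!name %in% names(x@layers)) stop(sprintf("no layer '%s' in stack", name))
  x@layers[[name]]
})

setMethod("length", "LayerStack", function(x) length(x@layers))

setMethod("show", "LayerStack", function(object) {
  cat(sprintf("LayerStack with %d layers\n", length(object@layers)))
  if (length(object@layers)) {
    d <- dim(object@layers[[1]]@values)
    cat(sprintf("  grid: %d x %d, cell %.3g km\n", d[1], d[2],
                object@layers[[1]]@cellKm))
    cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
  }
  invisible(object)
})

#' Subset a stack to named layers
#'
#' @param stack a [LayerStack-class].
#' @param names layer names to keep.
#' @return A [LayerStack-class].
#' @export
subsetStack <- function(stack, names) {
  missing <- setdiff(names, layerNames(stack))
  if (length(missing))
    stop("layers not in stack: ", paste(missing, collapse = ", "))
  layerStack(stack@layers[names],
             stack@provenance[intersect(names(stack@provenance), names)])
}

#' Extract layer values at cells as a matrix
#'
#' @param stack a [LayerStack-class].
#' @param cells linear cell indices (default: cells valid in every layer).
#' @return numeric matrix, one column per layer.
#' @export
stackValues <- function(stack, cells = NULL) {
  if (is.null(cells)) {
    ok <- Reduce(`&`, lapply(stack@layers, function(g) !is.na(g@values)))
    cells <- which(ok)
  }
  out <- vapply(stack@layers, function(g) g@values[cells],
                numeric(length(cells)))
  if (length(cells) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, names(stack@layers)))
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  out
}

# --- plain-text IO ----------------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Coordinates are the package's local equirectangular km system; a sidecar
#' `<file>.json` records the geographic origin so the grid round-trips.
#'
#' @param grid a [RasterGrid-class].
#' @param file output path (`.asc`).
#' @param digits significant digits written.
#' @export
writeAsciiGrid <- function(grid, file, digits = 7) {
  v <- grid@values
  nodata <- -9999
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid@xllKm),
    sprintf("yllcorner %.10g", grid@yllKm),
    sprintf("cellsize %.10g", grid@cellKm),
    sprintf("NODATA_value %d", nodata)), con)
  vv <- v; vv[is.na(vv)] <- nodata
  for (i in seq_len(nrow(vv)))
    writeLines(paste(signif(vv[i, ], digits), collapse = " "), con)
  jsonlite::write_json(list(refLon = grid@refLon, refLat = grid@refLat,
                            units = "km"),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid()]
#'
#' @param file path to the `.asc` file.
#' @return A [RasterGrid-class].
#' @export
readAsciiGrid <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- strsplit(hdr, "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  body <- scan(file, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  meta <- list(refLon = 25, refLat = 37)
  side <- paste0(file, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side)
  rasterGrid(m, cellKm = val[["cellsize"]], xllKm = val[["xllcorner"]],
             yllKm = val[["yllcorner"]], refLon = as.numeric(meta$refLon),
             refLat = as.numeric(meta$refLat))
}
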