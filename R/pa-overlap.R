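# basic polygon sanity: closed ring, >= 4 vertices, no self-intersection
checkPolygon <- function(ring, id) {
  if (nrow(ring) < 4 || any(ring[1, ] != ring[nrow(ring), ]))
    stop(sprintf("polygon %d is not a closed ring with >= 4 vertices", id))
  seg <- cbind(ring[-nrow(ring), , drop = FALSE], ring[-1, , drop = FALSE])
  n <- nrow(seg)
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the ring closure
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
        stop(sprintf("polygon %d self-intersects", id))
    }
  }
  invisible(TRUE)
}

#' Rasterize protected-area polygons onto a grid
#'
#' A cell is inside the mask iff its centre falls within any polygon
#' (cell-centre rule); sea (nodata) cells are always outside. Invalid
#' geometries (open or self-intersecting rings) raise an error naming the
#' polygon.
#'
#' @param polygons a `paSet` (list of closed `x`/`y` rings, km).
#' @param grid land [RasterGrid-class].
#' @return boolean [RasterGrid-class] (1 inside, 0 outside, NA on sea).
#' @export
rasterizePa <- function(polygons, grid) {
  cc <- cellCentersXY(grid)
  pts <- cbind(as.vector(cc$x), as.vector(cc$y))
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_along(polygons)) {
    ring <- polygons[[i]]
    checkPolygon(ring, i)
    inside <- inside | mgcv::in.out(ring, pts)
  }
  v <- matrix(as.numeric(inside), nrow(grid@values), ncol(grid@values))
  v[is.na(grid@values)] <- NA
  sameGrid(grid, v)
}

#' Fraction of hotspot cells inside protected areas
#'
#' @param hotspots a `HotspotSet`.
#' @param paMask boolean PA [RasterGrid-class] from [rasterizePa()].
#' @return list of class `OverlapReport`: `metric`, `scenario`,
#'   `nHotspotCells`, `nInside`, `fraction` (percent; `NA` and flagged when
#'   the hotspot set is empty).
#' @export
overlapFraction <- function(hotspots, paMask) {
  cells <- hotspots$cells$cell
  n <- length(cells)
  if (n == 0)
    return(structure(list(metric = hotspots$metric,
                          scenario = hotspots$scenario, nHotspotCells = 0,
                          nInside = 0, fraction = NA_real_, flagged = TRUE),
                     class = "OverlapReport"))
  inside <- paMask@values[cells]
  nIn <- sum(inside > 0, na.rm = TRUE)
  structure(list(metric = hotspots$metric, scenario = hotspots$scenario,
                 nHotspotCells = n, nInside = nIn,
                 fraction = 100 * nIn / n, flagged = FALSE),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("OverlapReport (%s, %s): %d of %d hotspot cells inside PAs (%s%%)\n",
              x$metric, x$scenario, x$nInside, x$nHotspotCells,
              if (is.na(x$fraction)) "NA" else sprintf("%.1f", x$fraction)))
  invisible(x)
}

#' Batch overlap table with a monotonic-trend summary
#'
#' @param hotspotList list of `HotspotSet`s (metric x scenario).
#' @param paMask boolean PA raster.
#' @param sliceOrder time-slice ordering used for the trend (default
#'   `c("current", "2020s", "2050s", "2080s")`).
#' @return data.frame (`metric`, `scenario`, `slice`, `nHotspotCells`,
#'   `nInside`, `fraction`) with attribute `trend`: per metric,
#'   `"decreasing"` when fractions are monotone non-increasing across
#'   slices, `"increasing"` when monotone non-decreasing, else `"mixed"`.
#' @export
overlapTable <- function(hotspotList, paMask,
                         sliceOrder = c("current", "2020s", "2050s", "2080s")) {
  rows <- lapply(hotspotList, function(h) {
    o <- overlapFraction(h, paMask)
    slice <- tail(strsplit(h$scenario, "|", fixed = TRUE)[[1]], 1)
    data.frame(metric = o$metric, scenario = h$scenario, slice = slice,
               nHotspotCells = o$nHotspotCells, nInside = o$nInside,
               fraction = o$fraction, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  trend <- vapply(unique(tab$metric), function(m) {
    sub <- tab[tab$metric == m, ]
    sub <- sub[order(match(sub$slice, sliceOrder)), ]
    f <- sub$fraction[!is.na(sub$fraction)]
    if (length(f) < 2) "undetermined"
    else if (all(diff(f) <= 0)) "decreasing"
    else if (all(diff(f) >= 0)) "increasing"
    else "mixed"
  }, "")
  attr(tab, "trend") <- trend
  tab
}
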