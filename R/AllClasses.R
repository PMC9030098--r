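#' @import methods
#' @importFrom stats quantile sd cor optim prcomp rnorm runif rbinom rpois
#'   kruskal.test fft setNames complete.cases var median mahalanobis
#'   cov predict glm binomial pnorm lm.fit
#' @importFrom utils head tail read.csv write.csv combn
NULL

#' Single-band georeferenced raster grid
#'
#' The universal spatial currency of the package: a numeric matrix on a local
#' equirectangular grid with square cells of a stated size in kilometres.
#' Row 1 is the northernmost row.  Sea / missing cells are `NA` (nodata).
#' Geographic coordinates are recovered through a reference origin
#' (`refLon`, `refLat`), the lon/lat of the grid's lower-left corner, so that
#' planar x/y in km and geographic lon/lat are linked by a linear map.
#'
#' @slot values numeric matrix, row 1 = north.
#' @slot cellKm cell side length in km.
#' @slot xllKm,yllKm planar coordinates (km) of the lower-left grid corner.
#' @slot refLon,refLat longitude/latitude (degrees) of the lower-left corner.
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    cellKm = "numeric",
    xllKm = "numeric",
    yllKm = "numeric",
    refLon = "numeric",
    refLat = "numeric"
  ),
  prototype(cellKm = 1, xllKm = 0, yllKm = 0, refLon = 25, refLat = 37)
)

setValidity("RasterGrid", function(object) {
  if (!is.numeric(object@values) && !is.logical(object@values))
    return("'values' must be a numeric or logical matrix")
  if (length(object@cellKm) != 1 || !is.finite(object@cellKm) || object@cellKm <= 0)
    return("'cellKm' must be a single positive number")
  if (abs(object@refLat) > 90) return("'refLat' out of range")
  TRUE
})

#' Named stack of aligned raster layers
#'
#' @slot layers named list of [RasterGrid-class] objects sharing one geometry.
#' @slot provenance named character vector of derivation notes per layer.
#' @export
setClass("LayerStack",
  representation(layers = "list", provenance = "character"),
  prototype(layers = list(), provenance = character(0))
)

setValidity("LayerStack", function(object) {
  nm <- names(object@layers)
  if (length(object@layers) && (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    return("layers must be uniquely named")
  if (!all(vapply(object@layers, is, TRUE, "RasterGrid")))
    return("all layers must be RasterGrid objects")
  if (length(object@layers) > 1) {
    d0 <- dim(object@layers[[1]]@values)
    ok <- vapply(object@layers, function(g) identical(dim(g@values), d0), TRUE)
    if (!all(ok)) return("all layers must share grid dimensions")
  }
  TRUE
})

#' Synthetic archipelago
#'
#' @slot dem elevation raster (m), `NA` on sea.
#' @slot landMask 0/1 raster, 1 on land; land is exactly `dem > 0`.
#' @slot settlements matrix with columns `x`, `y` (km, cell centres).
#' @slot seed integer seed the archipelago was generated from.
#' @export
setClass("Archipelago",
  representation(dem = "RasterGrid", landMask = "RasterGrid",
                 settlements = "matrix", seed = "integer"))

setValidity("Archipelago", function(object) {
  land <- !is.na(object@dem@values) & object@dem@values > 0
  mask <- object@landMask@values > 0 & !is.na(object@landMask@values)
  if (!identical(unname(land), unname(mask)))
    return("landMask must be true exactly where dem > 0")
  if (ncol(object@settlements) != 2) return("settlements must be an n x 2 matrix")
  TRUE
})

#' Monthly climate set
#'
#' Twelve monthly grids each of minimum temperature (degC), maximum
#' temperature (degC) and precipitation (mm/month), sharing one geometry.
#'
#' @slot tmin,tmax,prec lists of 12 [RasterGrid-class] objects (Jan..Dec).
#' @slot scenario scenario label, `"baseline"` or "gcm|rcp|slice".
#' @export
setClass("ClimateSet",
  representation(tmin = "list", tmax = "list", prec = "list",
                 scenario = "character"),
  prototype(scenario = "baseline"))

setValidity("ClimateSet", function(object) {
  if (length(object@tmin) != 12 || length(object@tmax) != 12 ||
      length(object@prec) != 12)
    return("tmin, tmax and prec must each hold 12 monthly grids")
  tmn <- vapply(object@tmin, function(g) list(g@values), list(1))
  for (m in 1:12) {
    a <- object@tmin[[m]]@values; b <- object@tmax[[m]]@values
    ok <- is.na(a) | is.na(b) | b >= a
    if (!all(ok)) return(sprintf("tmax < tmin in month %d", m))
    p <- object@prec[[m]]@values
    if (any(p < 0, na.rm = TRUE)) return(sprintf("negative precipitation in month %d", m))
  }
  TRUE
})

#' Virtual species with a known environmental niche
#'
#' Suitability is a product of Gaussian responses
#' `exp(-(x - opt)^2 / (2 tol^2))` over named predictor layers, optionally
#' restricted to a single island (component id) for endemics.
#'
#' @slot name species identifier.
#' @slot niche named list; each element `c(opt = , tol = )` keyed by layer name.
#' @slot prevalence intended approximate fraction of land that is suitable
#'   (informational; realized prevalence is an output of the generator).
#' @slot detectabilityDecay default per-km accessibility decay used when
#'   sampling occurrences.
#' @slot island island (connected-component) id the species is restricted to,
#'   or `NA_integer_` for no restriction.
#' @export
setClass("VirtualSpecies",
  representation(name = "character", niche = "list", prevalence = "numeric",
                 detectabilityDecay = "numeric", island = "integer"),
  prototype(prevalence = NA_real_, detectabilityDecay = 0, island = NA_integer_))

setValidity("VirtualSpecies", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name)) return("empty name")
  for (nm in names(object@niche)) {
    p <- object@niche[[nm]]
    if (!all(c("opt", "tol") %in% names(p)) || p[["tol"]] <= 0)
      return(sprintf("niche entry '%s' needs opt and tol > 0", nm))
  }
  TRUE
})

#' Ensemble of Small Models for one species
#'
#' Holds every fitted bivariate model with its cross-validated TSS weight,
#' the per-predictor training ranges used for clamping, pooled
#' cross-validation predictions, and the ensemble-level skill and maxSSS
#' threshold.
#'
#' @slot species species identifier.
#' @slot pairModels list; each element has `vars` (the two predictor names),
#'   `set` (pseudo-absence set id), `model` (fitted classifier), `weight`
#'   (mean cross-validated TSS, floored at 0) and `learner`.
#' @slot trainingRanges 2 x P matrix (`min`, `max` rows) over all predictors.
#' @slot ensembleTss cross-validated TSS of the weighted ensemble.
#' @slot threshold maxSSS threshold fitted on pooled CV predictions.
#' @slot cvPred data.frame of pooled cross-validation predictions
#'   (`label`, `pred`).
#' @slot modellable FALSE when every pair weight is zero.
#' @export
setClass("EsmEnsemble",
  representation(species = "character", pairModels = "list",
                 trainingRanges = "matrix", ensembleTss = "numeric",
                 threshold = "numeric", cvPred = "data.frame",
                 modellable = "logical"),
  prototype(modellable = TRUE))

setValidity("EsmEnsemble", function(object) {
  w <- vapply(object@pairModels, function(m) m$weight, 1)
  if (length(w) && any(w < 0)) return("pair weights must be >= 0")
  TRUE
})
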