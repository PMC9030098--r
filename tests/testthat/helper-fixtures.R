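# Shared fixtures, built once per test run (memoized).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fixArch <- function() fixture("arch", function()
  makeArchipelago(11, nIslands = 3, gridShape = c(80, 80)))

fixClim <- function() fixture("clim", function()
  makeMonthlyClimate(fixArch(), seed = 12))

fixBio <- function() fixture("bio", function() deriveBioclim(fixClim()))

fixFull <- function() fixture("full", function()
  combineStacks(fixBio(), deriveEnvirem(fixClim()),
                deriveTopographic(fixArch()@dem)))

fixRetained <- function() fixture("retained", function() {
  rep <- filterCollinear(fixFull(), samples = 3000,
                         keep = c("bio1", "bio12"), seed = 13)
  subsetStack(fixFull(), rep$retained)
})

# a climate set with the same scalar series in every cell of a small grid
toyClimate <- function(tmin, tmax, prec, nr = 4, nc = 4) {
  mk <- function(v) rasterGrid(matrix(v, nr, nc), cellKm = 1)
  new("ClimateSet", tmin = lapply(tmin, mk), tmax = lapply(tmax, mk),
      prec = lapply(prec, mk))
}

# a fully-random climate set (independent cell values) for quarter oracles
randomClimate <- function(seed, nr = 5, nc = 5) {
  set.seed(seed)
  mk <- function() rasterGrid(matrix(runif(nr * nc, -5, 25), nr, nc), cellKm = 1)
  tmin <- replicate(12, mk(), simplify = FALSE)
  tmax <- lapply(tmin, function(g) {
    g@values <- g@values + runif(length(g@values), 0.5, 12); g })
  prec <- replicate(12, {
    g <- mk(); g@values <- abs(g@values) * 10; g }, simplify = FALSE)
  new("ClimateSet", tmin = tmin, tmax = tmax, prec = prec)
}

# binary range map from a 0/1 matrix
toyRange <- function(m, species = "sp", scenario = "baseline") {
  binarizeSuitability(rasterGrid(m, cellKm = 1), 0.5, species, scenario)
}

# brute-force maximal thinning subset size (maximum independent set, n <= 15)
bruteThinOptimum <- function(lon, lat, thinDist) {
  n <- length(lon)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    geosphere::distHaversine(cbind(lon[i], lat[i]), cbind(lon[j], lat[j]),
                             r = 6371008.8) / 1000)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    okAll <- TRUE
    if (length(sel) > 1) {
      sub <- d[sel, sel]
      okAll <- all(sub[upper.tri(sub)] >= thinDist)
    }
    if (okAll) best <- length(sel)
  }
  best
}
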