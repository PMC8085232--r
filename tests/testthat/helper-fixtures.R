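# Shared fixture builders. Everything is generated in code from fixed seeds.

# Small grid over a synthetic mid-latitude window.
smallGrid <- function(nr = 40, nc = 40) {
  gridSpec(nr, nc, latMin = -30, latMax = -10, lonMin = 120, lonMax = 140)
}

# Small, well-watered landscape on which default parameters reach
# continental saturation within a few hundred generations.
smallLandscape <- function(seed = 3) {
  makeLandscape(smallGrid(), agesBP = seq(60000, 35000, by = -1000),
                wetFraction = 0.55, corLength = 5, seed = seed)
}

# Hand-built two-slice landscape with near-constant environment: a flat
# land strip (all land), tiny NPP gradient, water everywhere. Useful for
# travelling-wave and conservation checks where landscape randomness is
# unwanted.
stripLandscape <- function(nr = 5, nc = 30) {
  spec <- gridSpec(nr, nc, latMin = -12, latMax = -10, lonMin = 120,
                   lonMax = 135)
  elev <- matrix(100, nr, nc)
  ages <- c(60000, 35000)
  npp <- matrix(rep(seq(0.5, 0.6, length.out = nc), each = nr), nr, nc)
  new("PaleoLandscape",
    grid = spec, elevation = elev,
    ruggedness = matrix(0, nr, nc),
    distWater = matrix(0, nr, nc),
    basinMask = matrix(FALSE, nr, nc),
    ages = ages, seaLevel = c(-50, -50), lakeLevel = c(-Inf, -Inf),
    npp = list(npp, npp),
    landMask = list(matrix(TRUE, nr, nc), matrix(TRUE, nr, nc))
  )
}

# Scattered dated-record table over the small grid (not tied to any truth
# surface); for kriging/variogram mechanics.
scatterRecords <- function(n = 20, seed = 2) {
  set.seed(seed)
  data.frame(
    site = sprintf("s%02d", seq_len(n)),
    lon = runif(n, 120, 140), lat = runif(n, -30, -10),
    age_bp = runif(n, 30000, 50000), sd = runif(n, 100, 500),
    quality = "A", stringsAsFactors = FALSE
  )
}

# Variogram model with known parameters (no fitting).
fixedVariogram <- function(psill = 1e6, range = 500, nugget = 0) {
  new("VariogramModel", family = "exponential", nugget = nugget,
      psill = psill, rangeParam = range, empirical = data.frame())
}

# Gaussian random field at scattered points with exponential covariance
# (sill * exp(-d / range)), via the Cholesky factor. Independent oracle for
# variogram-recovery tests.
simulateGRF <- function(n, sill, range, seed) {
  set.seed(seed)
  lon <- runif(n, 120, 140)
  lat <- runif(n, -30, -10)
  D <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  C <- sill * exp(-D / range)
  z <- drop(t(chol(C + diag(sill * 1e-8, n))) %*% rnorm(n))
  data.frame(site = sprintf("g%03d", seq_len(n)), lon = lon, lat = lat,
             age_bp = 40000 + z, sd = 0, quality = "A",
             stringsAsFactors = FALSE)
}
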