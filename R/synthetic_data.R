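# Synthetic fixtures: landscapes with the statistical structure the model
# assumes (smooth elevation with a drowned shelf, autocorrelated NPP, a
# monotone sea-level curve, a lake basin, distance-to-water from a random
# wet mask) and dated records drawn from a known arrival surface under
# uniform-in-time taphonomic thinning.

# Largest 8-connected component of a logical mask (flood fill).
largestComponent <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    sz <- 0L
    while (length(stack)) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sz <- sz + 1L
      r <- (idx - 1L) %% nr + 1L
      cl <- (idx - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
    sizes[cur] <- sz
  }
  if (!cur) return(mask)
  lab == which.max(sizes)
}

# Spatially autocorrelated standard field: white noise convolved (circularly,
# via FFT) with a Gaussian kernel of SD sigma cells, rescaled to mean 0 / SD 1.
# The resulting correlogram is exp(-h^2 / (4 sigma^2)), i.e. it falls to 1/e
# at lag 2 * sigma.
smoothField <- function(nr, nc, sigmaCells) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigmaCells <= 0) return(z)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sigmaCells^2))
  kern <- kern / sum(kern)
  f <- Re(fft(fft(z) * fft(kern), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic palaeo-landscape
#'
#' Builds a [PaleoLandscape-class] with the structural features the
#' simulator expects: a smooth elevation field whose rank transform places a
#' prescribed fraction of cells on a continental shelf (between -120 m and
#' 0 m), deep sea below, and land up to `maxElev` above; a monotone
#' sea-level curve falling from `seaLevelRange[1]` at the oldest slice to
#' `seaLevelRange[2]` at the youngest (so the shelf emerges through time); a
#' shallow interior lake basin with its own falling level series (a
#' transient movement barrier); spatially autocorrelated NPP drifting
#' linearly between two smooth fields across slices; and distance-to-water
#' from a thresholded smooth field of wet cells.
#'
#' @param spec a [GridSpec-class].
#' @param agesBP slice ages (yr BP), oldest first, 1000-yr steps.
#' @param shelfFraction fraction of cells with elevation in (-120, 0) m.
#' @param deepFraction fraction of cells below -120 m.
#' @param maxElev maximum land elevation (m).
#' @param nppRange NPP range (kg C m^-2 yr^-1) spanned over land.
#' @param corLength autocorrelation length in cells: the lag at which the
#'   field correlogram falls to 1/e.
#' @param wetFraction fraction of cells that are wet (water sources).
#' @param seaLevelRange sea level (m) at the oldest and youngest slice.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A [PaleoLandscape-class].
#' @export
makeLandscape <- function(spec = gridSpec(),
                          agesBP = seq(85000, 40000, by = -1000),
                          shelfFraction = 0.15, deepFraction = 0.38,
                          maxElev = 1500,
                          nppRange = c(0.02, 1.4),
                          corLength = 8, wetFraction = 0.10,
                          seaLevelRange = c(-75, -95),
                          seed = 1) {
  if (shelfFraction < 0 || deepFraction < 0 ||
      shelfFraction + deepFraction >= 1)
    stop("impossible shelf/deep fractions: must be non-negative and sum to < 1")
  stopifnot(diff(range(agesBP)) > 0, nppRange[1] >= 0, nppRange[2] > nppRange[1])
  set.seed(seed)
  d <- dim(spec); nr <- d[1]; nc <- d[2]
  sigma <- corLength / 2
  ns <- length(agesBP)
  agesBP <- sort(agesBP, decreasing = TRUE)

  # elevation: rank-map a smooth field onto deep sea / shelf / land bands
  f <- smoothField(nr, nc, sigma)
  u <- rank(f, ties.method = "first") / (nr * nc)
  elev <- matrix(NA_real_, nr, nc)
  deep <- u <= deepFraction
  shelf <- u > deepFraction & u <= deepFraction + shelfFraction
  land <- !deep & !shelf
  elev[deep] <- -3000 + (u[deep] / max(deepFraction, 1e-12)) * (3000 - 120.001)
  elev[shelf] <- -120 + (u[shelf] - deepFraction) / max(shelfFraction, 1e-12) * 120
  elev[land] <- (u[land] - deepFraction - shelfFraction) /
    (1 - deepFraction - shelfFraction) * maxElev

  seaLevel <- seq(seaLevelRange[1], seaLevelRange[2], length.out = ns)

  # a continent, not an archipelago: keep only the largest connected
  # component of the maximally exposed land; stray islands sink below the
  # lowest sea level so every land cell is reachable on foot
  maxLand <- elev > min(seaLevel)
  comp <- largestComponent(maxLand)
  elev[maxLand & !comp] <- -3000

  # shallow interior lake basin: an ellipse of near-zero elevation whose
  # lake level falls from flooded to dry across the slices
  basin <- matrix(FALSE, nr, nc)
  br <- round(nr * 0.35); bc <- round(nc * 0.55)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (((i - br) / (nr * 0.06))^2 + ((j - bc) / (nc * 0.08))^2 <= 1)
      basin[i, j] <- TRUE
  }
  elev[basin] <- pmax(elev[basin], 1)
  lakeLevel <- seq(5, -10, length.out = ns)

  slices <- buildTimeSlices(elev, data.frame(age_bp = agesBP, level_m = seaLevel),
                            agesBP, basin,
                            data.frame(age_bp = agesBP, level_m = lakeLevel))

  # NPP: drift linearly between two smooth fields, mapped into nppRange
  g1 <- smoothField(nr, nc, sigma)
  g2 <- smoothField(nr, nc, sigma)
  toRange <- function(x) {
    nppRange[1] + (x - min(x)) / (max(x) - min(x)) * diff(nppRange)
  }
  npp <- lapply(seq_len(ns), function(s) {
    w <- if (ns == 1) 0 else (s - 1) / (ns - 1)
    toRange((1 - w) * g1 + w * g2)
  })

  wetField <- smoothField(nr, nc, sigma / 2)
  wet <- wetField > quantile(wetField, 1 - wetFraction)
  distW <- distanceToWater(wet)

  landUnion <- Reduce(`|`, slices$landMask)
  rug <- computeRuggedness(elev, standardizeOver = landUnion)

  new("PaleoLandscape",
    grid = spec, elevation = elev, ruggedness = rug, distWater = distW,
    basinMask = basin, ages = slices$ages, seaLevel = slices$seaLevel,
    lakeLevel = slices$lakeLevel, npp = npp, landMask = slices$landMask
  )
}

#' Planted first-arrival truth surface
#'
#' A smooth arrival-age gradient expanding from an entry cell at a constant
#' front rate: `A(x) = entryAgeBP - distanceKm(entry, x) / rate`.
#'
#' @param spec a [GridSpec-class].
#' @param mask logical matrix of cells on which the surface is defined.
#' @param entryCell integer `c(row, col)`.
#' @param entryAgeBP arrival age at the entry cell (yr BP).
#' @param rateKmPerYear front propagation rate. The default is slow enough
#'   that the planted surface spans far more than a typical taphonomic
#'   sampling window, which is what makes its spatial signal identifiable
#'   from uniformly thinned ages (see the methods vignette).
#' @return Matrix of arrival ages (yr BP), `NA` off the mask.
#' @export
makeArrivalTruth <- function(spec, mask, entryCell, entryAgeBP = 50000,
                             rateKmPerYear = 0.25) {
  cc <- cellCentres(spec)
  idx <- which(mask, arr.ind = TRUE)
  p0 <- c(cc$lon[entryCell[2]], cc$lat[entryCell[1]])
  dKm <- geosphere::distHaversine(cbind(cc$lon[idx[, 2]], cc$lat[idx[, 1]]),
                                  p0) / 1000
  out <- matrix(NA_real_, spec@nRows, spec@nCols)
  out[which(mask)] <- entryAgeBP - dKm / rateKmPerYear
  out
}

#' Sample dated records from a known arrival surface
#'
#' Sites are placed with configurable spatial clustering (cluster centres
#' uniform over eligible cells, members Gaussian-jittered around them) over
#' cells where the truth surface exceeds `A0`; each record's age is drawn
#' uniformly on `[A0, A(x_i)]` (the uniform-deposition taphonomic model),
#' with a dating SD drawn from `sigmaRange` and, optionally, Gaussian
#' measurement error of that SD added to the recorded age.
#'
#' @param truth matrix of true arrival ages (yr BP), `NA` off-domain.
#' @param spec a [GridSpec-class].
#' @param n number of records.
#' @param A0 reference age (yr BP); sites need `A(x) > A0`.
#' @param clusterSdCells Gaussian jitter SD (cells) of sites around their
#'   cluster centre; 0 disables clustering (uniform sites).
#' @param sitesPerCluster average cluster size.
#' @param sigmaRange dating-SD sampling interval (yr).
#' @param addNoise add Gaussian measurement error to the recorded ages.
#' @param seed RNG seed.
#' @return data.frame with `site`, `lon`, `lat`, `age_bp`, `sd`, `quality`
#'   and the helper columns `row`, `col`, `true_arrival`.
#' @export
makeDates <- function(truth, spec, n = 150, A0 = NULL,
                      clusterSdCells = 3, sitesPerCluster = 10,
                      sigmaRange = c(100, 800), addNoise = FALSE, seed = 1) {
  set.seed(seed)
  if (is.null(A0)) A0 <- min(truth, na.rm = TRUE)
  elig <- which(!is.na(truth) & truth > A0, arr.ind = TRUE)
  if (nrow(elig) < 1) stop("no cells with arrival age above A0")
  if (n > nrow(elig) * 1000)
    stop("requested more records than the eligible domain supports")
  pick <- integer(0)
  if (clusterSdCells > 0) {
    nClust <- max(3L, ceiling(n / sitesPerCluster))
    centres <- elig[sample.int(nrow(elig), nClust, replace = TRUE), , drop = FALSE]
    while (length(pick) < n) {
      ci <- sample.int(nClust, 1)
      r <- round(centres[ci, 1] + rnorm(1, 0, clusterSdCells))
      cl <- round(centres[ci, 2] + rnorm(1, 0, clusterSdCells))
      hit <- which(elig[, 1] == r & elig[, 2] == cl)
      if (length(hit)) pick <- c(pick, hit[1])
    }
  } else {
    pick <- sample.int(nrow(elig), n, replace = TRUE)
  }
  rows <- elig[pick, 1]; cols <- elig[pick, 2]
  cc <- cellCentres(spec)
  Ax <- truth[cbind(rows, cols)]
  ages <- runif(n, A0, Ax)
  sds <- runif(n, sigmaRange[1], sigmaRange[2])
  obs <- if (addNoise) ages + rnorm(n, 0, sds) else ages
  # sites sit anywhere within their cell, not at the centre, so repeated
  # draws of one cell still give distinct locations
  dlat <- (spec@latMax - spec@latMin) / spec@nRows
  dlon <- (spec@lonMax - spec@lonMin) / spec@nCols
  data.frame(
    site = sprintf("synthsite_%03d", seq_len(n)),
    lon = cc$lon[cols] + runif(n, -dlon / 2, dlon / 2),
    lat = cc$lat[rows] + runif(n, -dlat / 2, dlat / 2),
    age_bp = obs, sd = sds, quality = "A",
    row = rows, col = cols, true_arrival = Ax,
    stringsAsFactors = FALSE
  )
}
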