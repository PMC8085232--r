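# Landscape construction: ruggedness, time slices, downscaling and
# between-slice interpolation.

#' Topographic ruggedness index, min-max standardized
#'
#' Per cell, the root-mean-square of the elevation differences to the eight
#' neighbouring cells; edge cells use their available neighbours. The raw
#' index is then min-max standardized to \[0, 1\] over the cells of
#' `standardizeOver` (default: all cells; pass a land mask to standardize
#' over land only). A flat field degenerates to all zeros.
#'
#' @param elevation numeric matrix (m); at least 3 x 3.
#' @param standardizeOver optional logical matrix; cells over which the
#'   min-max standardization is computed.
#' @param raw if `TRUE`, return the unstandardized index.
#' @return Numeric matrix; standardized ruggedness in \[0, 1\] (or the raw
#'   RMS index).
#' @examples
#' e <- matrix(0, 3, 3); e[2, 2] <- 10
#' computeRuggedness(e, raw = TRUE)[2, 2] # 10
#' @export
computeRuggedness <- function(elevation, standardizeOver = NULL, raw = FALSE) {
  stopifnot(is.matrix(elevation), nrow(elevation) >= 3, ncol(elevation) >= 3)
  nr <- nrow(elevation); nc <- ncol(elevation)
  ssq <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr) # rows with a neighbour at -dr? see below
    # shifted neighbour value at (i, j) is elevation[i + dr, j + dc]
    ri <- seq_len(nr); ci <- seq_len(nc)
    riOK <- ri + dr >= 1 & ri + dr <= nr
    ciOK <- ci + dc >= 1 & ci + dc <= nc
    d <- elevation[ri[riOK], ci[ciOK], drop = FALSE] -
      elevation[ri[riOK] + dr, ci[ciOK] + dc, drop = FALSE]
    ssq[ri[riOK], ci[ciOK]] <- ssq[ri[riOK], ci[ciOK]] + d^2
    cnt[ri[riOK], ci[ciOK]] <- cnt[ri[riOK], ci[ciOK]] + 1
  }
  tri <- sqrt(ssq / cnt)
  if (raw) return(tri)
  sel <- if (is.null(standardizeOver)) rep(TRUE, length(tri)) else as.vector(standardizeOver)
  lo <- min(tri[sel]); hi <- max(tri[sel])
  if (hi - lo <= 0) return(matrix(0, nr, nc)) # no relief: degenerate
  out <- (tri - lo) / (hi - lo)
  pmin(pmax(out, 0), 1)
}

#' Build 1000-year time slices of the land mask
#'
#' A cell is land in a slice when its elevation exceeds that slice's sea
#' level; cells inside the named lake basin are additionally masked when the
#' basin's lake level floods them.
#'
#' @param elevation numeric matrix (m).
#' @param seaLevelSeries data.frame with columns `age_bp` and `level_m`
#'   covering the requested ages.
#' @param ages numeric vector of slice ages (yr BP), oldest first.
#' @param basinMask optional logical matrix of the lake basin.
#' @param lakeLevelSeries optional data.frame (`age_bp`, `level_m`) of lake
#'   levels; required when `basinMask` has any `TRUE` cell.
#' @return A list with `ages`, `seaLevel`, `lakeLevel` and `landMask` (list of
#'   logical matrices).
#' @export
buildTimeSlices <- function(elevation, seaLevelSeries, ages,
                            basinMask = NULL, lakeLevelSeries = NULL) {
  stopifnot(is.matrix(elevation), all(c("age_bp", "level_m") %in% names(seaLevelSeries)))
  if (is.null(basinMask)) basinMask <- matrix(FALSE, nrow(elevation), ncol(elevation))
  ages <- sort(ages, decreasing = TRUE)
  lookup <- function(series, age, what) {
    hit <- which(series$age_bp == age)
    if (!length(hit))
      stop("no ", what, " entry for slice at ", age, " yr BP")
    series$level_m[hit[1]]
  }
  sl <- vapply(ages, function(a) lookup(seaLevelSeries, a, "sea-level"), 0)
  if (any(basinMask)) {
    if (is.null(lakeLevelSeries))
      stop("lakeLevelSeries required when basinMask is non-empty")
    ll <- vapply(ages, function(a) lookup(lakeLevelSeries, a, "lake-level"), 0)
  } else ll <- rep(-Inf, length(ages))
  masks <- lapply(seq_along(ages), function(s) {
    m <- elevation > sl[s]
    m[basinMask & elevation <= ll[s]] <- FALSE
    m
  })
  list(ages = ages, seaLevel = sl, lakeLevel = ll, landMask = masks)
}

#' Bilinear downscaling of a coarse grid to the model lattice
#'
#' Interpolates a coarse regular grid (given by its node coordinates) at the
#' fine-grid cell centres. Values at coincident nodes are preserved; target
#' points outside the coarse hull are filled from the nearest edge (with a
#' message).
#'
#' @param coarse numeric matrix, rows ordered north to south like the model
#'   grid.
#' @param coarseLat,coarseLon numeric node coordinates of `coarse`
#'   (`coarseLat` decreasing, `coarseLon` increasing).
#' @param spec a [GridSpec-class] describing the target lattice.
#' @return Numeric matrix of dimensions `dim(spec)`.
#' @export
downscaleBilinear <- function(coarse, coarseLat, coarseLon, spec) {
  stopifnot(is.matrix(coarse), length(coarseLat) == nrow(coarse),
            length(coarseLon) == ncol(coarse))
  if (any(diff(coarseLat) >= 0)) stop("coarseLat must be decreasing (north first)")
  if (any(diff(coarseLon) <= 0)) stop("coarseLon must be increasing")
  cc <- cellCentres(spec)
  clamped <- FALSE
  clamp <- function(x, lo, hi) {
    if (any(x < lo | x > hi)) clamped <<- TRUE
    pmin(pmax(x, lo), hi)
  }
  # work in increasing-latitude space for findInterval
  latAsc <- rev(coarseLat)
  tLat <- clamp(cc$lat, min(coarseLat), max(coarseLat))
  tLon <- clamp(cc$lon, min(coarseLon), max(coarseLon))
  iLat <- pmin(pmax(findInterval(tLat, latAsc), 1L), length(latAsc) - 1L)
  iLon <- pmin(pmax(findInterval(tLon, coarseLon), 1L), length(coarseLon) - 1L)
  fLat <- (tLat - latAsc[iLat]) / (latAsc[iLat + 1L] - latAsc[iLat])
  fLon <- (tLon - coarseLon[iLon]) / (coarseLon[iLon + 1L] - coarseLon[iLon])
  # map ascending-lat index back to matrix row (row 1 = north)
  rowHi <- nrow(coarse) - iLat + 1L      # row of latAsc[iLat] (southern node)
  rowLo <- rowHi - 1L                    # row of latAsc[iLat + 1] (northern node)
  out <- matrix(NA_real_, spec@nRows, spec@nCols)
  for (i in seq_len(spec@nRows)) {
    v00 <- coarse[rowHi[i], iLon]        # south-west
    v01 <- coarse[rowHi[i], iLon + 1L]   # south-east
    v10 <- coarse[rowLo[i], iLon]        # north-west
    v11 <- coarse[rowLo[i], iLon + 1L]   # north-east
    out[i, ] <- (1 - fLat[i]) * ((1 - fLon) * v00 + fLon * v01) +
      fLat[i] * ((1 - fLon) * v10 + fLon * v11)
  }
  if (clamped) message("downscaleBilinear: targets outside the coarse hull filled from the nearest edge")
  out
}

#' Environment at an arbitrary age: between-slice interpolation
#'
#' NPP is interpolated linearly per cell between the two bracketing
#' 1000-year slices; the land mask and sea level are taken from the nearest
#' slice. Ages outside the slice span are an error.
#'
#' @param landscape a [PaleoLandscape-class].
#' @param ageBP age in years BP.
#' @return A list with `npp` (matrix), `landMask` (logical matrix),
#'   `seaLevel` and `age`.
#' @export
interpolateGenerations <- function(landscape, ageBP) {
  ages <- landscape@ages
  if (ageBP > max(ages) + 1e-9 || ageBP < min(ages) - 1e-9)
    stop("age ", ageBP, " yr BP outside the slice span (",
         max(ages), " .. ", min(ages), ")")
  interpolateStack(landscape@npp, ages, ageBP, landscape@landMask, landscape@seaLevel)
}

# Shared linear interpolation over an age-indexed list of matrices (ages
# strictly decreasing). Used for NPP and for carrying-capacity stacks.
interpolateStack <- function(stack, ages, ageBP, landMask = NULL, seaLevel = NULL) {
  iNear <- which.min(abs(ages - ageBP))
  hit <- which(abs(ages - ageBP) < 1e-9)
  if (length(hit)) {
    val <- stack[[hit[1]]]
    iLo <- hit[1]
  } else {
    iOld <- max(which(ages > ageBP))   # older bracketing slice
    iYng <- iOld + 1L                  # younger bracketing slice
    w <- (ages[iOld] - ageBP) / (ages[iOld] - ages[iYng])
    val <- (1 - w) * stack[[iOld]] + w * stack[[iYng]]
    iLo <- iOld
  }
  out <- list(npp = val, age = ageBP)
  if (!is.null(landMask)) out$landMask <- landMask[[iNear]]
  if (!is.null(seaLevel)) out$seaLevel <- seaLevel[iNear]
  out
}

#' Distance to water in cell units
#'
#' Euclidean distance (in cells) from each cell to the nearest wet cell.
#' Cells that are themselves wet have distance zero.
#'
#' @param wetMask logical matrix of wet cells.
#' @return Numeric matrix of distances; `Inf` if no wet cell exists.
#' @export
distanceToWater <- function(wetMask) {
  stopifnot(is.matrix(wetMask))
  nr <- nrow(wetMask); nc <- ncol(wetMask)
  wet <- which(wetMask, arr.ind = TRUE)
  if (nrow(wet) == 0) return(matrix(Inf, nr, nc))
  cppDistanceToWater(nr, nc, wet[, 1], wet[, 2])
}
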