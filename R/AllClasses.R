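#' @import methods
#' @importFrom stats rpois rbeta rnorm runif rexp median quantile var sd cor
#'   optim setNames fft
#' @importFrom utils head read.csv write.csv
#' @useDynLib paleospread, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Grid specification for the half-degree palaeo-landscape lattice
#'
#' Describes the raster lattice on which all grids in the package live.
#' Cells are indexed `(row, col)` with row 1 the northernmost latitude band.
#' The default corresponds to a 0.5-degree grid spanning 0.5--43.0 degrees S
#' and 110.5--153.5 degrees E (86 rows by 87 columns), with a nominal
#' east-west cell width of 0.5 x 111.12 = 55.56 km and a cell area of
#' 3080.25 km^2.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot latMin,latMax,lonMin,lonMax numeric extent in decimal degrees
#'   (latitudes negative in the southern hemisphere).
#' @slot cellAreaKm2 numeric area of one cell in km^2.
#' @slot cellWidthKm numeric nominal width of one cell in km.
#'
#' @seealso [gridSpec()]
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer",
    latMin = "numeric", latMax = "numeric",
    lonMin = "numeric", lonMax = "numeric",
    cellAreaKm2 = "numeric", cellWidthKm = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "grid must have at least one row and one column")
    if (object@latMin >= object@latMax) msg <- c(msg, "latMin must be < latMax")
    if (object@lonMin >= object@lonMax) msg <- c(msg, "lonMin must be < lonMax")
    if (object@cellAreaKm2 <= 0) msg <- c(msg, "cellAreaKm2 must be positive")
    if (object@cellWidthKm <= 0) msg <- c(msg, "cellWidthKm must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param latMin,latMax,lonMin,lonMax extent in decimal degrees.
#' @param cellAreaKm2 cell area in km^2.
#' @param cellWidthKm nominal cell width in km; the default is half of
#'   111.12 km (one half-degree of arc).
#' @return A [GridSpec-class] object.
#' @examples
#' gs <- gridSpec()
#' dim(gs)
#' @export
gridSpec <- function(nRows = 86L, nCols = 87L,
                     latMin = -43.0, latMax = -0.5,
                     lonMin = 110.5, lonMax = 153.5,
                     cellAreaKm2 = 3080.25,
                     cellWidthKm = 0.5 * 111.12) {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    latMin = latMin, latMax = latMax, lonMin = lonMin, lonMax = lonMax,
    cellAreaKm2 = cellAreaKm2, cellWidthKm = cellWidthKm
  )
}

#' @describeIn GridSpec grid dimensions as `c(nRows, nCols)`.
#' @param x a `GridSpec`.
#' @export
setMethod("dim", "GridSpec", function(x) c(x@nRows, x@nCols))

#' Cell-centre coordinates of a grid
#'
#' @param spec a [GridSpec-class].
#' @return A list with `lat` (length `nRows`, north to south) and `lon`
#'   (length `nCols`, west to east) cell-centre coordinates in degrees.
#' @export
cellCentres <- function(spec) {
  dlat <- (spec@latMax - spec@latMin) / spec@nRows
  dlon <- (spec@lonMax - spec@lonMin) / spec@nCols
  list(
    lat = spec@latMax - dlat * (seq_len(spec@nRows) - 0.5),
    lon = spec@lonMin + dlon * (seq_len(spec@nCols) - 0.5)
  )
}

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@nRows, "x", object@nCols, "cells\n")
  cat("  lat:", object@latMin, "..", object@latMax,
      " lon:", object@lonMin, "..", object@lonMax, "\n")
  cat("  cell:", object@cellWidthKm, "km wide,",
      object@cellAreaKm2, "km^2\n")
})

#' Time-varying gridded palaeo-environment
#'
#' Holds the static layers (elevation, standardized ruggedness,
#' distance-to-water, the lake-basin mask) plus the 1000-year time slices of
#' the environment: per-slice land mask, net primary production (NPP,
#' kg C m^-2 yr^-1) and sea level. Slice ages are years before present, in
#' decreasing-age order.
#'
#' @slot grid a [GridSpec-class].
#' @slot elevation numeric matrix, metres relative to modern sea level.
#' @slot ruggedness numeric matrix in \[0, 1\] (min-max standardized
#'   topographic ruggedness index over land).
#' @slot distWater numeric matrix, distance to the nearest water cell in cell
#'   units.
#' @slot basinMask logical matrix marking the enclosed lake basin whose level
#'   is tracked separately from the ocean.
#' @slot ages numeric vector of slice ages (yr BP, multiples of 1000).
#' @slot seaLevel numeric vector of sea levels (m) per slice.
#' @slot lakeLevel numeric vector of lake levels (m) per slice.
#' @slot npp list of NPP matrices, one per slice.
#' @slot landMask list of logical matrices, one per slice.
#' @export
setClass("PaleoLandscape",
  representation(
    grid = "GridSpec",
    elevation = "matrix", ruggedness = "matrix", distWater = "matrix",
    basinMask = "matrix",
    ages = "numeric", seaLevel = "numeric", lakeLevel = "numeric",
    npp = "list", landMask = "list"
  ),
  validity = function(object) {
    d <- dim(object@grid)
    msg <- character()
    for (nm in c("elevation", "ruggedness", "distWater", "basinMask")) {
      if (!identical(dim(slot(object, nm)), d))
        msg <- c(msg, paste0(nm, " dimensions do not match the grid"))
    }
    ns <- length(object@ages)
    if (length(object@seaLevel) != ns || length(object@npp) != ns ||
        length(object@landMask) != ns)
      msg <- c(msg, "per-slice layers must match length(ages)")
    if (ns > 1 && any(diff(object@ages) >= 0))
      msg <- c(msg, "ages must be strictly decreasing (oldest first)")
    if (any(object@distWater < 0, na.rm = TRUE))
      msg <- c(msg, "distWater must be non-negative")
    for (s in seq_len(ns)) {
      land <- object@landMask[[s]]
      if (any(object@npp[[s]][land] < 0, na.rm = TRUE)) {
        msg <- c(msg, "NPP must be non-negative on land")
        break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "PaleoLandscape", function(object) {
  d <- dim(object@grid)
  cat("PaleoLandscape:", d[1], "x", d[2], "cells,",
      length(object@ages), "time slices\n")
  if (length(object@ages)) {
    cat("  ages:", max(object@ages), "..", min(object@ages), "yr BP\n")
    cat("  land cells (oldest slice):", sum(object@landMask[[1]]), "\n")
  }
})

#' @describeIn PaleoLandscape slice ages in years BP (oldest first).
#' @param object,x a `PaleoLandscape`.
#' @export
setGeneric("sliceAges", function(x) standardGeneric("sliceAges"))

#' @rdname PaleoLandscape-class
#' @export
setMethod("sliceAges", "PaleoLandscape", function(x) x@ages)

#' @describeIn PaleoLandscape land mask of the slice nearest an age.
#' @export
setGeneric("landMaskAt", function(x, ageBP) standardGeneric("landMaskAt"))

#' @rdname PaleoLandscape-class
#' @param ageBP age in years BP.
#' @export
setMethod("landMaskAt", "PaleoLandscape", function(x, ageBP) {
  x@landMask[[which.min(abs(x@ages - ageBP))]]
})

#' Per-cell population state of the automaton
#'
#' @slot N numeric matrix of abundances (people per cell; integers by
#'   construction, sea cells zero).
#' @slot generation integer generation counter.
#' @slot firstArrival numeric matrix; generation at which the cell first
#'   reached the occupancy threshold, `NA` while unset. Set at most once.
#' @export
setClass("PopulationState",
  representation(N = "matrix", generation = "integer", firstArrival = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@N), dim(object@firstArrival)))
      msg <- c(msg, "N and firstArrival dimensions differ")
    if (any(object@N < 0, na.rm = TRUE)) msg <- c(msg, "N must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an empty population state
#'
#' @param spec a [GridSpec-class].
#' @return A [PopulationState-class] with zero abundance everywhere.
#' @export
emptyState <- function(spec) {
  d <- dim(spec)
  new("PopulationState",
    N = matrix(0, d[1], d[2]),
    generation = 0L,
    firstArrival = matrix(NA_real_, d[1], d[2])
  )
}

setMethod("show", "PopulationState", function(object) {
  cat("PopulationState: generation", object@generation,
      "| total N =", sum(object@N),
      "| occupied cells =", sum(object@N > 0),
      "| cells arrived =", sum(!is.na(object@firstArrival)), "\n")
})

#' @describeIn PopulationState total population.
#' @param x a `PopulationState`.
#' @export
setGeneric("totalPopulation", function(x) standardGeneric("totalPopulation"))

#' @rdname PopulationState-class
#' @export
setMethod("totalPopulation", "PopulationState", function(x) sum(x@N))

#' A single entry/dispersal scenario
#'
#' A scenario combines the timing of first entry, the entry sequence and the
#' assumed carrying-capacity--NPP relationship. Sequences follow the
#' convention: `"S"` (southern entry only), `"N"` (northern only), `"SN"`
#' (simultaneous), `"S-N"` (south first, north 72 generations later) and
#' `"N-S"` (north first, south 72 generations later).
#'
#' @slot entryAgeKa numeric entry age in ka (thousands of years BP).
#' @slot sequence character, one of `"S"`, `"N"`, `"SN"`, `"S-N"`, `"N-S"`.
#' @slot kModel character, one of `"linear"`, `"parabolic"`, `"qyd"`.
#' @slot foundersRange numeric length-2; founding group size drawn uniformly
#'   in this interval at each entry event.
#' @slot entryLagGenerations integer lag of the second entry for the staged
#'   sequences (72 generations, about 2000 years).
#' @export
setClass("Scenario",
  representation(
    entryAgeKa = "numeric", sequence = "character", kModel = "character",
    foundersRange = "numeric", entryLagGenerations = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@sequence %in% c("S", "N", "SN", "S-N", "N-S"))
      msg <- c(msg, "unknown entry sequence")
    if (!object@kModel %in% c("linear", "parabolic", "qyd"))
      msg <- c(msg, "unknown K model")
    if (length(object@foundersRange) != 2 || diff(object@foundersRange) < 0)
      msg <- c(msg, "foundersRange must be an increasing length-2 vector")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Scenario
#'
#' @param entryAgeKa entry age in ka.
#' @param sequence entry sequence code (see [Scenario-class]).
#' @param kModel carrying-capacity relationship: `"linear"`, `"parabolic"` or
#'   `"qyd"`.
#' @param foundersRange uniform sampling interval for the founding group size.
#' @param entryLagGenerations lag (generations) of the staged second entry.
#' @return A [Scenario-class].
#' @export
scenario <- function(entryAgeKa = 50, sequence = "S", kModel = "parabolic",
                     foundersRange = c(1300, 1500),
                     entryLagGenerations = 72L) {
  new("Scenario",
    entryAgeKa = entryAgeKa, sequence = sequence, kModel = kModel,
    foundersRange = foundersRange,
    entryLagGenerations = as.integer(entryLagGenerations)
  )
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf(
    "Scenario: entry %g ka, sequence %s, K model %s, founders %g-%g\n",
    object@entryAgeKa, object@sequence, object@kModel,
    object@foundersRange[1], object@foundersRange[2]
  ))
})

#' @describeIn Scenario compact scenario identifier, e.g. `"S_50_parabolic"`.
#' @param x a `Scenario`.
#' @export
setGeneric("scenarioId", function(x) standardGeneric("scenarioId"))

#' @rdname Scenario-class
#' @export
setMethod("scenarioId", "Scenario", function(x) {
  sprintf("%s_%g_%s", x@sequence, x@entryAgeKa, x@kModel)
})

#' Ensemble summary of repeated scenario runs
#'
#' @slot meanArrival,loArrival,hiArrival numeric matrices of per-cell first
#'   arrival (generations since entry): mean, 2.5 and 97.5 percentiles over
#'   iterations (over the iterations in which the cell was reached).
#' @slot trajectories numeric matrix, total population per generation (rows)
#'   by iteration (columns).
#' @slot saturationGeneration numeric per-iteration generation at which every
#'   land cell had been occupied to the threshold; `NA` when never reached.
#' @slot nIter integer number of iterations.
#' @slot nFirst numeric occupancy threshold used for first arrival.
#' @slot scenario the [Scenario-class] that was run.
#' @export
setClass("EnsembleResult",
  representation(
    meanArrival = "matrix", loArrival = "matrix", hiArrival = "matrix",
    trajectories = "matrix", saturationGeneration = "numeric",
    nIter = "integer", nFirst = "numeric", scenario = "Scenario"
  ),
  validity = function(object) {
    msg <- character()
    ok <- is.na(object@loArrival) | is.na(object@hiArrival) |
      (object@loArrival <= object@hiArrival + 1e-9)
    if (!all(ok)) msg <- c(msg, "percentile maps must bracket each other")
    if (length(object@saturationGeneration) != object@nIter)
      msg <- c(msg, "one saturation value per iteration required")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "EnsembleResult", function(object) {
  sat <- object@saturationGeneration
  cat("EnsembleResult:", scenarioId(object@scenario),
      "|", object@nIter, "iterations\n")
  cat("  cells reached (any iteration):", sum(!is.na(object@meanArrival)), "\n")
  if (any(!is.na(sat))) {
    cat("  saturation generations:", min(sat, na.rm = TRUE), "-",
        max(sat, na.rm = TRUE),
        sprintf("(%d/%d iterations saturated)\n", sum(!is.na(sat)), length(sat)))
  } else cat("  saturation: never reached\n")
})

#' Fitted variogram model
#'
#' Semivariance model \eqn{\gamma(u)} with nugget, partial sill and range
#' parameter; the implied covariance is \eqn{c(u) = \sigma^2 - \gamma(u)}
#' with total sill \eqn{\sigma^2} = nugget + partial sill.
#'
#' @slot family character; `"exponential"`, `"spherical"` or `"gaussian"`.
#' @slot nugget,psill,rangeParam numeric parameters (psill = partial sill;
#'   rangeParam in the same distance units as the fitted distances, km here).
#' @slot empirical data.frame of the binned empirical semivariogram
#'   (`dist`, `gamma`, `n`), kept for diagnostics.
#' @export
setClass("VariogramModel",
  representation(
    family = "character", nugget = "numeric", psill = "numeric",
    rangeParam = "numeric", empirical = "data.frame"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% c("exponential", "spherical", "gaussian"))
      msg <- c(msg, "unknown variogram family")
    if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
    if (object@psill < 0) msg <- c(msg, "partial sill must be >= 0")
    if (object@rangeParam <= 0) msg <- c(msg, "range must be > 0")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel (%s): nugget = %.4g, partial sill = %.4g, range = %.4g\n",
    object@family, object@nugget, object@psill, object@rangeParam
  ))
})

#' Bias-corrected first-arrival surface
#'
#' @slot estimate numeric matrix of corrected terminal (first-arrival) ages,
#'   yr BP; `NA` off the evaluation mask.
#' @slot sdMap numeric matrix of per-cell standard deviations over replicates.
#' @slot prelim numeric matrix of the preliminary (uncorrected) surface.
#' @slot krigedMean numeric matrix of the kriged mean age.
#' @slot A0 numeric reference (youngest assumed-presence) age, yr BP.
#' @slot k integer number of bias-correction replicates.
#' @export
setClass("ArrivalSurface",
  representation(
    estimate = "matrix", sdMap = "matrix", prelim = "matrix",
    krigedMean = "matrix", A0 = "numeric", k = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@estimate), dim(object@sdMap)) ||
        !identical(dim(object@estimate), dim(object@prelim)))
      msg <- c(msg, "surface layer dimensions differ")
    if (any(object@estimate < object@A0 - 1e-6, na.rm = TRUE))
      msg <- c(msg, "estimate must be >= A0 wherever defined")
    if (object@k < 2) msg <- c(msg, "k must be >= 2")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ArrivalSurface", function(object) {
  cat("ArrivalSurface:", sum(!is.na(object@estimate)), "cells,",
      object@k, "replicates, A0 =", object@A0, "yr BP\n")
  if (any(!is.na(object@estimate)))
    cat("  corrected ages:", round(min(object@estimate, na.rm = TRUE)), "-",
        round(max(object@estimate, na.rm = TRUE)), "yr BP\n")
})

#' @describeIn ArrivalSurface corrected arrival-age matrix (yr BP).
#' @param x an `ArrivalSurface`.
#' @export
setGeneric("arrivalEstimate", function(x) standardGeneric("arrivalEstimate"))

#' @rdname ArrivalSurface-class
#' @export
setMethod("arrivalEstimate", "ArrivalSurface", function(x) x@estimate)

#' @describeIn ArrivalSurface per-cell replicate standard deviation.
#' @export
setGeneric("arrivalSD", function(x) standardGeneric("arrivalSD"))

#' @rdname ArrivalSurface-class
#' @export
setMethod("arrivalSD", "ArrivalSurface", function(x) x@sdMap)
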