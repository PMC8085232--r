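# Scenario orchestration: the per-generation update loop, entry seeding,
# ensembles, first-arrival maps and saturation metrics.

#' Build the full scenario factor grid
#'
#' Cartesian product of entry ages, entry sequences and carrying-capacity
#' relationships, in deterministic order (kModel fastest, entry age slowest).
#' The defaults enumerate the 8 x 5 x 3 = 120 member grid.
#'
#' @param entryAgesKa numeric entry ages (ka).
#' @param sequences character entry sequences (see [Scenario-class]).
#' @param kModels character K--NPP relationships.
#' @param foundersRange,entryLagGenerations passed to [scenario()].
#' @return List of [Scenario-class] objects.
#' @export
buildScenarioGrid <- function(entryAgesKa = seq(85, 50, by = -5),
                              sequences = c("S", "N", "SN", "S-N", "N-S"),
                              kModels = c("linear", "parabolic", "qyd"),
                              foundersRange = c(1300, 1500),
                              entryLagGenerations = 72L) {
  if (!length(entryAgesKa) || !length(sequences) || !length(kModels))
    stop("every scenario factor needs at least one level")
  if (anyDuplicated(entryAgesKa) || anyDuplicated(sequences) ||
      anyDuplicated(kModels))
    stop("duplicate factor levels are not allowed")
  out <- list()
  for (age in entryAgesKa) for (sq in sequences) for (km in kModels) {
    out[[length(out) + 1L]] <- scenario(age, sq, km, foundersRange,
                                        entryLagGenerations)
  }
  out
}

#' Snap a cell to the nearest land cell of a slice
#'
#' @param landscape a [PaleoLandscape-class].
#' @param ageBP age (yr BP) selecting the nearest slice's land mask.
#' @param cell integer `c(row, col)`.
#' @return Integer `c(row, col)` of the nearest land cell.
#' @export
nearestLandCell <- function(landscape, ageBP, cell) {
  mask <- landMaskAt(landscape, ageBP)
  if (mask[cell[1], cell[2]]) return(as.integer(cell))
  land <- which(mask, arr.ind = TRUE)
  if (nrow(land) == 0) stop("no land cells at ", ageBP, " yr BP")
  d2 <- (land[, 1] - cell[1])^2 + (land[, 2] - cell[2])^2
  as.integer(land[which.min(d2), ])
}

#' Seed a founding population at an entry cell
#'
#' Draws the founding group size uniformly in `foundersRange` and adds it at
#' the entry cell. Errors when the entry cell is under water at the seeding
#' age.
#'
#' @param state a [PopulationState-class].
#' @param cell integer `c(row, col)` entry cell.
#' @param foundersRange length-2 uniform sampling interval.
#' @param landMask logical matrix at the seeding age.
#' @param ageBP the seeding age (used only in the error message).
#' @return The updated [PopulationState-class].
#' @export
seedEntry <- function(state, cell, foundersRange, landMask, ageBP = NA) {
  if (!landMask[cell[1], cell[2]])
    stop("entry cell (", cell[1], ", ", cell[2], ") is under water at ",
         ageBP, " yr BP")
  founders <- round(runif(1, foundersRange[1], foundersRange[2]))
  state@N[cell[1], cell[2]] <- state@N[cell[1], cell[2]] + founders
  state
}

# Relocate occupants of cells that are no longer land (or have zero K) to
# the nearest land cell; remove them if no land exists.
relocateDrowned <- function(N, landMask) {
  bad <- which(N > 0 & !landMask)
  if (!length(bad)) return(N)
  land <- which(landMask, arr.ind = TRUE)
  nr <- nrow(N)
  for (idx in bad) {
    people <- N[idx]
    N[idx] <- 0
    if (nrow(land) == 0) next # continent fully drowned: population lost
    r0 <- (idx - 1L) %% nr + 1L
    c0 <- (idx - 1L) %/% nr + 1L
    d2 <- (land[, 1] - r0)^2 + (land[, 2] - c0)^2
    tgt <- land[which.min(d2), ]
    N[tgt[1], tgt[2]] <- N[tgt[1], tgt[2]] + people
  }
  N
}

#' Advance the automaton by one generation
#'
#' Ordered sub-steps: (1) refresh the environment and carrying capacity at
#' this generation's age (between-slice interpolation plus Poisson
#' resampling); (2) Ricker growth; (3) neighbour exchange; (4) long-distance
#' dispersal; (5) clustered catastrophes; (6) the MVP penalty; (7)
#' relocation of occupants of drowned cells; (8) first-arrival bookkeeping
#' for cells newly at or above `nFirst`.
#'
#' @param state a [PopulationState-class].
#' @param landscape a [PaleoLandscape-class].
#' @param kStack list of per-slice K matrices (see [computeKStack()]).
#' @param ageBP age (yr BP) of this generation.
#' @param demog a [demographyParams()] list.
#' @param disp a [dispersalParams()] list.
#' @param thomas a [thomasParams()] list.
#' @param catIntensityScale catastrophe intensity calibration constant.
#' @param nFirst occupancy threshold for first arrival.
#' @return The updated [PopulationState-class].
#' @export
runGeneration <- function(state, landscape, kStack, ageBP,
                          demog = demographyParams(),
                          disp = dispersalParams(),
                          thomas = thomasParams(),
                          catIntensityScale = 0,
                          nFirst = 100) {
  env <- interpolateGenerations(landscape, ageBP)
  kInterp <- interpolateStack(kStack, landscape@ages, ageBP)$npp
  kInterp[!env$landMask] <- 0
  K <- resampleK(kInterp, env$landMask)
  N <- state@N
  if (any(N > 0)) {
    nppRel <- env$npp / max(env$npp[env$landMask], 1e-12)
    nppRel[nppRel <= 0] <- 1e-3
    N <- rickerGrowth(N, K, demog$rMax)
    N <- neighbourExchange(N, K, landscape@ruggedness, disp)
    N <- longDistanceDispersal(N, K, env$landMask, landscape@distWater,
                               nppRel, landscape@ruggedness, disp,
                               landscape@grid@cellWidthKm)
    if (catIntensityScale > 0 && demog$pCat > 0) {
      cells <- sampleCatastropheCells(N > 0, thomas, catIntensityScale)
      N <- applyCatastrophes(N, cells, demog$mCat)
    }
    N <- applyMvpPenalty(N, demog$nMVP, demog$mMVP)
    N <- relocateDrowned(N, env$landMask)
  }
  state@N <- N
  state@generation <- state@generation + 1L
  newly <- which(is.na(state@firstArrival) & N >= nFirst)
  state@firstArrival[newly] <- state@generation
  state
}

#' Run a scenario ensemble
#'
#' Runs `nIter` independent replicates of a scenario over `horizon`
#' generations, with per-replicate seeds derived from the master seed, and
#' aggregates per-cell mean and 2.5/97.5-percentile first-arrival maps, the
#' total-population trajectories and the per-replicate saturation
#' generation (the generation at which every land cell of the then-current
#' mask had been occupied to at least `nFirst` people at least once).
#'
#' @param scn a [Scenario-class].
#' @param landscape a [PaleoLandscape-class]; its slices must span the
#'   scenario horizon.
#' @param entryCells named list with `S` and/or `N` entry cells
#'   (`c(row, col)`), as required by the scenario sequence.
#' @param demog,disp,thomas parameter lists.
#' @param nIter number of replicates.
#' @param seed master seed.
#' @param horizon number of generations per replicate.
#' @param nFirst occupancy threshold for first arrival.
#' @param bounds a [densityBounds()] list.
#' @param calibrateCatastrophes calibrate and apply clustered catastrophes
#'   (disable for speed in diagnostics).
#' @param catIntensityScale pre-computed catastrophe calibration constant;
#'   when supplied the internal calibration is skipped.
#' @return An [EnsembleResult-class].
#' @export
runScenario <- function(scn, landscape, entryCells,
                        demog = demographyParams(),
                        disp = dispersalParams(),
                        thomas = thomasParams(),
                        nIter = 100, seed = 1, horizon = 300,
                        nFirst = 100, bounds = densityBounds(),
                        calibrateCatastrophes = TRUE,
                        catIntensityScale = NULL) {
  entryBP <- scn@entryAgeKa * 1000
  endBP <- entryBP - horizon * demog$generationYears
  if (entryBP > max(landscape@ages) || endBP < min(landscape@ages))
    stop("landscape slices (", max(landscape@ages), "..", min(landscape@ages),
         " yr BP) do not span the scenario horizon (", entryBP, "..",
         round(endBP), " yr BP)")
  kStack <- computeKStack(landscape, scn@kModel, bounds)
  d <- dim(landscape@grid)

  set.seed(seed)
  iterSeeds <- sample.int(.Machine$integer.max - 1L, nIter)
  catScale <- 0
  if (!is.null(catIntensityScale)) {
    catScale <- catIntensityScale
  } else if (calibrateCatastrophes && demog$pCat > 0) {
    # reference occupancy: half of the land cells at entry age
    mask0 <- landMaskAt(landscape, entryBP)
    ref <- matrix(FALSE, d[1], d[2])
    landIdx <- which(mask0)
    ref[sample(landIdx, length(landIdx) %/% 2)] <- TRUE
    catScale <- calibrateCatastropheIntensity(ref, thomas, demog$pCat)
  }

  entries <- scheduleEntries(scn, entryCells)
  arr <- array(NA_real_, c(d[1], d[2], nIter))
  traj <- matrix(0, horizon, nIter)
  satGen <- rep(NA_real_, nIter)

  for (it in seq_len(nIter)) {
    set.seed(iterSeeds[it])
    state <- emptyState(landscape@grid)
    for (t in seq_len(horizon)) {
      ageBP <- entryBP - (t - 1) * demog$generationYears
      due <- entries[entries$generation == t - 1L, , drop = FALSE]
      if (nrow(due)) {
        mask <- landMaskAt(landscape, ageBP)
        for (e in seq_len(nrow(due))) {
          cell <- c(due$row[e], due$col[e])
          state <- seedEntry(state, cell, scn@foundersRange, mask, ageBP)
        }
      }
      state <- runGeneration(state, landscape, kStack, ageBP, demog, disp,
                             thomas, catScale, nFirst)
      traj[t, it] <- sum(state@N)
      if (is.na(satGen[it])) {
        mask <- landMaskAt(landscape, ageBP)
        if (all(!is.na(state@firstArrival[mask]))) satGen[it] <- t
      }
    }
    arr[, , it] <- state@firstArrival
  }

  reached <- apply(!is.na(arr), c(1, 2), any)
  meanA <- loA <- hiA <- matrix(NA_real_, d[1], d[2])
  idx <- which(reached)
  for (ix in idx) {
    r <- (ix - 1L) %% d[1] + 1L; cc <- (ix - 1L) %/% d[1] + 1L
    v <- arr[r, cc, ]
    v <- v[!is.na(v)]
    meanA[ix] <- mean(v)
    q <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    loA[ix] <- q[1]; hiA[ix] <- q[2]
  }
  new("EnsembleResult",
    meanArrival = meanA, loArrival = loA, hiArrival = hiA,
    trajectories = traj, saturationGeneration = satGen,
    nIter = as.integer(nIter), nFirst = nFirst, scenario = scn
  )
}

# Entry schedule implied by a scenario: data.frame(generation, row, col).
scheduleEntries <- function(scn, entryCells) {
  need <- switch(scn@sequence,
    "S" = list(c("S", 0L)),
    "N" = list(c("N", 0L)),
    "SN" = list(c("S", 0L), c("N", 0L)),
    "S-N" = list(c("S", 0L), c("N", scn@entryLagGenerations)),
    "N-S" = list(c("N", 0L), c("S", scn@entryLagGenerations))
  )
  rows <- lapply(need, function(x) {
    cell <- entryCells[[x[1]]]
    if (is.null(cell))
      stop("scenario sequence ", scn@sequence, " needs an entry cell named '",
           x[1], "'")
    data.frame(generation = as.integer(x[2]), row = cell[1], col = cell[2])
  })
  do.call(rbind, rows)
}

#' Great-circle distance between two grid cells
#'
#' @param spec a [GridSpec-class].
#' @param cellA,cellB integer `c(row, col)` cells.
#' @return Distance in km (haversine on cell centres).
#' @export
cellDistanceKm <- function(spec, cellA, cellB) {
  cc <- cellCentres(spec)
  a <- c(cc$lon[cellA[2]], cc$lat[cellA[1]])
  b <- c(cc$lon[cellB[2]], cc$lat[cellB[1]])
  geosphere::distHaversine(a, b) / 1000
}

#' Saturation timing and rate of spread
#'
#' Summarizes an ensemble's saturation distribution as a generation range,
#' the equivalent years (generations times generation length) and the
#' implied front rate from the entry cell to a far reference cell
#' (great-circle distance divided by years). Never-saturated ensembles
#' return `NA` values rather than an error.
#'
#' @param ensemble an [EnsembleResult-class].
#' @param entryCell,farCell integer `c(row, col)` cells.
#' @param spec the [GridSpec-class] of the run.
#' @param generationYears generation length in years.
#' @return List with `generations` (min, max), `years` (min, max),
#'   `distanceKm` and `rateKmPerYear` (min, max).
#' @export
saturationMetrics <- function(ensemble, entryCell, farCell, spec,
                              generationYears = 27.9) {
  sat <- ensemble@saturationGeneration
  sat <- sat[!is.na(sat)]
  distKm <- cellDistanceKm(spec, entryCell, farCell)
  if (!length(sat)) {
    return(list(generations = c(NA_real_, NA_real_),
                years = c(NA_real_, NA_real_),
                distanceKm = distKm,
                rateKmPerYear = c(NA_real_, NA_real_)))
  }
  gens <- range(sat)
  years <- gens * generationYears
  rate <- if (distKm == 0) c(0, 0) else rev(distKm / years)
  list(generations = gens, years = years, distanceKm = distKm,
       rateKmPerYear = rate)
}
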