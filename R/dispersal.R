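# Dispersal: neighbour-cell emigration/immigration and long-distance
# dispersal, modulated by productivity, water availability and terrain
# ruggedness. The per-cell sequential passes are implemented in C++
# (src/dispersal.cpp) using R's RNG for reproducibility; the scalar pieces
# are exposed here for direct use and testing.

#' Emigration probability as a function of the carrying-capacity ratio
#'
#' `Pr(E) = exp(-coef * Krel)` where `Krel` is the ratio of the focal cell's
#' carrying capacity to the neighbouring cell's: emigration towards a better
#' cell becomes more likely the steeper the gradient.
#'
#' @param Krel non-negative carrying-capacity ratio (focal / neighbour).
#' @param coef decay coefficient.
#' @return Probability in (0, 1\].
#' @examples
#' emigrationProbability(1) # exp(-3.2) ~ 0.0408
#' @export
emigrationProbability <- function(Krel, coef = 3.2) {
  stopifnot(all(Krel >= 0))
  exp(-coef * Krel)
}

#' Allometric maximum natal dispersal distance
#'
#' `D_m = a * M^b` for adult body mass `M` (kg). With the central mammalian
#' omnivore/herbivore coefficients (a = 3.31, b = 0.65) and M = 50 kg this
#' gives about 42.1 km; the one-SD parameter corners give 22.4 and 69.3 km.
#'
#' @param massKg adult body mass in kg.
#' @param a,b allometric coefficients.
#' @return Distance in km.
#' @export
allometricMaxDistance <- function(massKg = 50, a = 3.31, b = 0.65) {
  if (any(massKg <= 0)) stop("body mass must be positive")
  a * massKg^b
}

#' Radius of the circle with a given area
#'
#' Converts a mobility area (km^2 per generation) into an equivalent
#' circular foraging radius, for comparison with dispersal distances.
#'
#' @param areaKm2 area in km^2.
#' @return Radius in km.
#' @examples
#' mobilityRadius(c(1400, 3900, 2600)) # 21.1, 35.2, 28.8 km
#' @export
mobilityRadius <- function(areaKm2) {
  stopifnot(all(areaKm2 >= 0))
  sqrt(areaKm2 / pi)
}

#' Water-limited probability of realizing a long-distance dispersal
#'
#' The default form is `P_l = 1 - (D_H2O / D_l)^omega`, clamped to \[0, 1\]:
#' resistance grows as the destination sits further from water, vanishing
#' when water is in the cell and absolute when the distance to water reaches
#' the dispersal distance itself. The literal published form with the ratio
#' inverted (`1 - (D_l / D_H2O)^omega`) is available with `literal = TRUE`;
#' it makes resistance *fall* in the driest cells and is kept only for
#' comparison.
#'
#' @param Dl realized dispersal distance (cell units).
#' @param DH2O distance to water (cell units).
#' @param omega hydrological resistance exponent.
#' @param literal use the non-inverted ratio.
#' @return Probability in \[0, 1\].
#' @examples
#' waterLimitedProbability(2, 1, 3) # 1 - (1/2)^3 = 0.875
#' @export
waterLimitedProbability <- function(Dl, DH2O, omega = 3, literal = FALSE) {
  stopifnot(all(Dl > 0), all(DH2O >= 0), omega > 0)
  p <- if (literal) 1 - (Dl / DH2O)^omega else 1 - (DH2O / Dl)^omega
  pmin(pmax(p, 0), 1)
}

#' Ruggedness movement factor
#'
#' The proportion of intended migrants that actually move, as a function of
#' standardized ruggedness: `Mred = a + b * Grel^(1/3)` gives the retained
#' proportion, whose complement (the reduction, at most about 1% with the
#' default coefficients) is scaled by the resistance modifier `R`; the
#' result is clamped to \[0, 1\].
#'
#' @param Grel standardized ruggedness in \[0, 1\].
#' @param R resistance modifier scaling the reduction.
#' @param a,b curve coefficients.
#' @return Movement factor in \[0, 1\].
#' @examples
#' ruggednessFactor(1) # about 0.9907: <1% reduction even at maximum relief
#' @export
ruggednessFactor <- function(Grel, R = 1, a = 1.001116, b = -0.0104453) {
  stopifnot(all(Grel >= 0), all(Grel <= 1))
  mRed <- a + b * Grel^(1 / 3)
  pmin(pmax(1 - R * (1 - mRed), 0), 1)
}

#' Sample a long-distance dispersal displacement
#'
#' The dispersal scale is the allometric maximum distance inflated by
#' `prodScale^(-log10(nppRel))` -- a `prodScale`-fold increase per tenfold
#' decrease in relative NPP -- and capped at `dCellMax * cellWidthKm`. A
#' distance is drawn from the exponential exceedance law
#' `Pr(d >= x) = exp(-x / scale)`, converted to cell units and
#' Poisson-resampled into integer axis displacements with independent random
#' signs.
#'
#' @param dMaxKm allometric maximum dispersal distance (km).
#' @param nppRel relative NPP of the source cell, in (0, 1\].
#' @param cellWidthKm cell width (km).
#' @param dCellMax scale cap in cell widths.
#' @param prodScale productivity inflation factor.
#' @return Integer vector `c(dx, dy)` (columns east, rows south positive).
#' @export
sampleLddDistance <- function(dMaxKm, nppRel, cellWidthKm = 55.56,
                              dCellMax = 10, prodScale = 12.7) {
  stopifnot(dMaxKm > 0, nppRel > 0, nppRel <= 1)
  scale <- min(dMaxKm * prodScale^(-log10(nppRel)), dCellMax * cellWidthKm)
  dCells <- rexp(1, rate = 1 / scale) / cellWidthKm
  d <- rpois(2, dCells)
  d * sign(runif(2) - 0.5)
}

#' Neighbour-cell emigration/immigration pass
#'
#' Processes every occupied focal cell in row-major order. A focal cell
#' whose N/K ratio exceeds a uniform fission threshold on
#' (`fissionLo`, `fissionHi`) considers its eight neighbours in the order
#' NW, N, NE, W, E, SW, S, SE; whenever the carrying-capacity ratio
#' `Krel = K_focal / K_neighbour` is below 1, emigration occurs with
#' probability `exp(-emigCoef * Krel)`, moving a beta-resampled proportion
#' (mean `pMig`, CV `cvMig`) of the people *remaining* in the source, scaled
#' by the source cell's ruggedness movement factor and stochastically
#' rounded. Sea neighbours (K = 0) are skipped. Total population is
#' conserved exactly.
#'
#' @param N numeric matrix of abundances.
#' @param K numeric matrix of (already Poisson-resampled) carrying
#'   capacities; 0 marks sea.
#' @param ruggedness standardized ruggedness matrix in \[0, 1\].
#' @param params a [dispersalParams()] list.
#' @return Updated abundance matrix.
#' @export
neighbourExchange <- function(N, K, ruggedness, params = dispersalParams()) {
  stopifnot(identical(dim(N), dim(K)), identical(dim(N), dim(ruggedness)))
  rug <- ruggednessFactor(ruggedness, params$R, params$rugA, params$rugB)
  cppNeighbourExchange(N, K, rug, params$pMig, params$cvMig,
                       params$fissionLo, params$fissionHi, params$emigCoef)
}

#' Long-distance dispersal pass
#'
#' Each occupied cell meeting the fission condition attempts exactly one
#' long-distance event per generation: a displacement is drawn as in
#' [sampleLddDistance()] (using the source cell's relative NPP), the event is
#' accepted with the water-limited probability evaluated at the realized
#' distance and the *target* cell's distance-to-water, and on acceptance a
#' migrant group (same sizing rules as neighbour exchange, ruggedness-scaled)
#' moves to the target if it is land within the grid. Rejected, off-grid,
#' sea-target or zero-displacement events move nobody. Population is
#' conserved exactly.
#'
#' @param N numeric matrix of abundances.
#' @param K numeric matrix of carrying capacities (0 on sea).
#' @param landMask logical matrix.
#' @param distWater distance-to-water matrix (cell units).
#' @param nppRel relative NPP matrix in (0, 1\].
#' @param ruggedness standardized ruggedness matrix.
#' @param params a [dispersalParams()] list.
#' @param cellWidthKm cell width in km.
#' @return Updated abundance matrix.
#' @export
longDistanceDispersal <- function(N, K, landMask, distWater, nppRel,
                                  ruggedness, params = dispersalParams(),
                                  cellWidthKm = 55.56) {
  stopifnot(identical(dim(N), dim(K)))
  rug <- ruggednessFactor(ruggedness, params$R, params$rugA, params$rugB)
  cppLongDistanceDispersal(
    N, K, landMask * 1, distWater, nppRel, rug,
    params$pMig, params$cvMig, params$fissionLo, params$fissionHi,
    params$dMaxKm, cellWidthKm, params$dCellMax * params$dCellMult,
    params$prodScale, params$omega, isTRUE(params$waterLiteral)
  )
}
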