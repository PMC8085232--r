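# Parameter constructors. Plain lists (not S4): these are bags of scalars that
# users tweak wholesale, in the style of glm.control().

#' Demographic parameters
#'
#' Defaults follow the model's study conditions: generation length 27.9 yr,
#' minimum viable population 100 people with a beta-resampled extra mortality
#' centred on 0.2 below that threshold, and catastrophic mortality striking a
#' cell with probability 0.14 per generation at a beta-sampled severity
#' centred on 0.5 (SD 0.05). The maximum per-generation growth rate `rMax`
#' defaults to 0.205, the midpoint of its 0.10--0.31 plausible range.
#'
#' @param rMax maximum per-generation population growth rate.
#' @param generationYears length of one human generation, years.
#' @param nMVP minimum viable population (people).
#' @param mMVP mean additional mortality proportion below `nMVP`
#'   (beta-resampled, SD `mMVP / 10`).
#' @param pCat per-generation, per-cell probability of a catastrophic
#'   mortality event (long-run marginal rate of the clustered process).
#' @param mCat mean catastrophe mortality proportion (beta, SD `mCat / 10`).
#' @return A named list of demographic parameters.
#' @export
demographyParams <- function(rMax = 0.205, generationYears = 27.9,
                             nMVP = 100, mMVP = 0.2,
                             pCat = 0.14, mCat = 0.5) {
  stopifnot(rMax > 0, generationYears > 0, nMVP >= 0,
            mMVP >= 0, mMVP <= 1, pCat >= 0, pCat <= 1, mCat >= 0, mCat <= 1)
  list(rMax = rMax, generationYears = generationYears, nMVP = nMVP,
       mMVP = mMVP, pCat = pCat, mCat = mCat)
}

#' Thomas cluster-process parameters for catastrophe placement
#'
#' Parents are a Poisson process whose intensity is linear in the occupied
#' fraction of the grid between `kappaRange[1]` and `kappaRange[2]` (times a
#' calibration constant, see [calibrateCatastropheIntensity()]); offspring are
#' displaced from the parent with an axis-wise Gaussian SD of `sigmaScale`
#' times the grid dimension, and each parent spawns on average `muFactor`
#' times the mean dimension of the occupied bounding box offspring.
#'
#' @param kappaRange length-2 increasing parent-intensity endpoints.
#' @param sigmaScale grid-normalized offspring displacement SD.
#' @param muFactor mean offspring per parent, as a multiple of the mean
#'   occupied-grid dimension.
#' @return A named list.
#' @export
thomasParams <- function(kappaRange = c(0.3, 1.2), sigmaScale = 0.015,
                         muFactor = 0.6) {
  stopifnot(length(kappaRange) == 2, diff(kappaRange) > 0, sigmaScale > 0,
            muFactor > 0)
  list(kappaRange = kappaRange, sigmaScale = sigmaScale, muFactor = muFactor)
}

#' Dispersal parameters
#'
#' Neighbour-cell emigration and long-distance dispersal settings. The
#' fission ("budding-off") trigger is a uniform draw on
#' (`fissionLo`, `fissionHi`) compared against N/K; emigration probability
#' decays as `exp(-emigCoef * Krel)` in the carrying-capacity ratio of the
#' focal to the neighbouring cell. The migrating group is a beta-resampled
#' proportion centred on `pMig` (coefficient of variation `cvMig`) of the
#' people remaining in the source. Long-distance dispersal uses the
#' allometric maximum natal dispersal distance `a * M^b` (`allomA`, `allomB`,
#' `bodyMassKg`), inflated by `prodScale`-fold per tenfold drop in relative
#' NPP, capped at `dCellMax` cell widths, with water limitation exponent
#' `omega` and ruggedness-resistance modifier `R` (see [ruggednessFactor()]).
#'
#' @param pMig mean migrating proportion.
#' @param cvMig coefficient of variation of the beta-resampled proportion.
#' @param fissionLo,fissionHi N/K bounds of the uniform fission trigger.
#' @param emigCoef exponential decay coefficient of emigration probability.
#' @param allomA,allomB allometric coefficients of maximum natal dispersal.
#' @param bodyMassKg adult body mass used in the allometry.
#' @param dMaxKm maximum natal dispersal distance in km; defaults to
#'   `allomA * bodyMassKg^allomB`.
#' @param dCellMax hard cap on the dispersal scale, in cell widths.
#' @param dCellMult sensitivity modifier multiplying `dCellMax` (1--5).
#' @param prodScale fold-increase in dispersal distance per tenfold decrease
#'   in relative net primary production.
#' @param omega hydrological resistance exponent.
#' @param rugA,rugB coefficients of the ruggedness movement-reduction curve.
#' @param R ruggedness-resistance modifier scaling the reduction.
#' @param waterLiteral use the literal (non-inverted) form of the water
#'   limitation; see [waterLimitedProbability()].
#' @return A named list of dispersal parameters.
#' @export
dispersalParams <- function(pMig = 1 / 3, cvMig = 0.05,
                            fissionLo = 0.3, fissionHi = 0.7,
                            emigCoef = 3.2,
                            allomA = 3.31, allomB = 0.65, bodyMassKg = 50,
                            dMaxKm = allomA * bodyMassKg^allomB,
                            dCellMax = 10, dCellMult = 1,
                            prodScale = 12.7, omega = 3,
                            rugA = 1.001116, rugB = -0.0104453, R = 1,
                            waterLiteral = FALSE) {
  stopifnot(pMig >= 0, pMig < 1, cvMig >= 0,
            fissionLo > 0, fissionLo < fissionHi, fissionHi <= 1,
            dMaxKm > 0, dCellMax >= 1, dCellMult > 0, omega > 0, R >= 0)
  list(pMig = pMig, cvMig = cvMig, fissionLo = fissionLo,
       fissionHi = fissionHi, emigCoef = emigCoef,
       allomA = allomA, allomB = allomB, bodyMassKg = bodyMassKg,
       dMaxKm = dMaxKm, dCellMax = dCellMax, dCellMult = dCellMult,
       prodScale = prodScale, omega = omega,
       rugA = rugA, rugB = rugB, R = R, waterLiteral = waterLiteral)
}

#' Human density bounds used to scale NPP into carrying capacity
#'
#' @param dMin,dMax minimum and maximum hunter-gatherer densities
#'   (people km^-2) used to rescale NPP.
#' @param cellAreaKm2 cell area (km^2) converting density to people per cell.
#' @return A named list.
#' @export
densityBounds <- function(dMin = 0.018, dMax = 1.152, cellAreaKm2 = 3080.25) {
  stopifnot(dMin > 0, dMax > dMin, cellAreaKm2 > 0)
  list(dMin = dMin, dMax = dMax, cellAreaKm2 = cellAreaKm2)
}

# Moment-matched beta draw: n draws with the given mean and SD. Degenerate
# SDs (0, or infeasible for the mean) fall back to the mean itself.
rbetaMoment <- function(n, mean, sd) {
  if (mean <= 0 || mean >= 1 || sd <= 0) return(rep(mean, n))
  v <- sd^2
  f <- mean * (1 - mean) / v - 1
  if (f <= 0) return(rep(mean, n)) # SD too large for a beta; use the mean
  rbeta(n, mean * f, (1 - mean) * f)
}

# Beta shape parameters for a given mean and SD (exported for transparency in
# tests and docs).

#' Beta shape parameters by moment matching
#'
#' @param mean,sd target mean and standard deviation; must satisfy
#'   `sd^2 < mean * (1 - mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' betaShapes(0.5, 0.05) # alpha = beta = 49.5
#' @export
betaShapes <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0, sd^2 < mean * (1 - mean))
  f <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * f, beta = (1 - mean) * f)
}

# Stochastic rounding: floor plus a Bernoulli draw on the fractional part,
# preserving expectation while keeping people countable.
stochasticRound <- function(x) {
  f <- floor(x)
  frac <- x - f
  f + (runif(length(x)) < frac)
}
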