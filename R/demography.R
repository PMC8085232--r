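# Per-generation demographic updates: Ricker growth, the minimum-viable-
# population penalty, and spatially clustered catastrophic mortality.

#' Ricker population growth
#'
#' Applies `N' = N * exp(rMax * (1 - N / K))` per cell and stochastically
#' rounds the result (floor plus Bernoulli on the fraction), preserving the
#' expectation while keeping abundances integer. Cells with `K <= 0` but
#' `N > 0` (e.g. freshly drowned shelf cells) are left unchanged here; the
#' simulator's relocation step deals with them.
#'
#' @param N numeric matrix of abundances.
#' @param K numeric matrix of carrying capacities.
#' @param rMax maximum per-generation growth rate.
#' @param round apply stochastic rounding (disable to inspect expectations).
#' @return Updated abundance matrix.
#' @examples
#' set.seed(1)
#' mean(replicate(200, rickerGrowth(matrix(50), matrix(100), 0.2)[1, 1]))
#' # close to 50 * exp(0.1) = 55.26
#' @export
rickerGrowth <- function(N, K, rMax, round = TRUE) {
  stopifnot(identical(dim(N), dim(K)), rMax > 0)
  out <- N
  idx <- which(N > 0 & K > 0)
  if (length(idx)) {
    g <- N[idx] * exp(rMax * (1 - N[idx] / K[idx]))
    out[idx] <- if (round) stochasticRound(g) else g
  }
  out
}

#' Minimum-viable-population mortality penalty
#'
#' Cells with `0 < N < nMVP` lose a beta-resampled proportion of their
#' population centred on `mMVP` (SD `mMVP / 10`), emulating inbreeding
#' depression and Allee effects in small groups.
#'
#' @param N numeric matrix of abundances.
#' @param nMVP minimum viable population size (people).
#' @param mMVP mean mortality proportion applied below the threshold.
#' @param round stochastically round survivors to integers.
#' @return Updated abundance matrix.
#' @export
applyMvpPenalty <- function(N, nMVP = 100, mMVP = 0.2, round = TRUE) {
  idx <- which(N > 0 & N < nMVP)
  if (length(idx)) {
    loss <- rbetaMoment(length(idx), mMVP, mMVP / 10)
    surv <- N[idx] * (1 - loss)
    N[idx] <- if (round) stochasticRound(surv) else surv
  }
  N
}

#' Sample catastrophe-struck cells from a Thomas cluster process
#'
#' Cluster parents are a Poisson number of points placed uniformly over the
#' whole grid, with expected count
#' `intensityScale * (kappaRange[1] + diff(kappaRange) * occupiedFraction)`.
#' Each parent spawns a Poisson number of offspring (mean `muFactor` times
#' the mean dimension of the occupied bounding box), displaced from the
#' parent by independent axis-wise Gaussian noise with SD `sigmaScale` times
#' the grid dimension. Offspring falling on occupied cells mark those cells
#' as struck. `intensityScale` is the calibration constant from
#' [calibrateCatastropheIntensity()] that pins the long-run hit fraction to
#' the target marginal catastrophe probability.
#'
#' @param occupiedMask logical matrix of occupied cells.
#' @param thomas a [thomasParams()] list.
#' @param intensityScale calibration constant multiplying the parent
#'   intensity (0 disables catastrophes).
#' @return Integer vector of struck cell indices (into the matrix), possibly
#'   empty.
#' @export
sampleCatastropheCells <- function(occupiedMask, thomas = thomasParams(),
                                   intensityScale = 1) {
  occ <- which(occupiedMask, arr.ind = TRUE)
  if (nrow(occ) == 0 || intensityScale <= 0) return(integer(0))
  nr <- nrow(occupiedMask); nc <- ncol(occupiedMask)
  rr <- range(occ[, 1]); cr <- range(occ[, 2])
  meanDim <- mean(c(diff(rr) + 1, diff(cr) + 1))
  mu <- thomas$muFactor * meanDim
  occFrac <- nrow(occ) / (nr * nc)
  kappa <- intensityScale *
    (thomas$kappaRange[1] + diff(thomas$kappaRange) * occFrac)
  nPar <- rpois(1, kappa)
  if (nPar == 0) return(integer(0))
  # parents are uniform over the whole grid so the per-cell strike rate does
  # not depend on how widely the population has spread
  parR <- runif(nPar, 0.5, nr + 0.5)
  parC <- runif(nPar, 0.5, nc + 0.5)
  nOff <- rpois(nPar, mu)
  tot <- sum(nOff)
  if (tot == 0) return(integer(0))
  offR <- rep(parR, nOff) + rnorm(tot, 0, thomas$sigmaScale * nr)
  offC <- rep(parC, nOff) + rnorm(tot, 0, thomas$sigmaScale * nc)
  ri <- as.integer(round(offR)); ci <- as.integer(round(offC))
  keep <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(keep)) return(integer(0))
  idx <- unique((ci[keep] - 1L) * nr + ri[keep])
  idx[occupiedMask[idx]]
}

#' Calibrate the catastrophe parent intensity
#'
#' Finds, by bisection on the simulated hit rate, the global scaling constant
#' of the Thomas-process parent intensity such that the long-run mean
#' fraction of occupied cells struck per generation equals `pCat`.
#'
#' @param occupiedMask logical matrix of a reference occupancy pattern.
#' @param thomas a [thomasParams()] list.
#' @param pCat target marginal per-cell catastrophe probability per
#'   generation.
#' @param nGen generations simulated per bisection evaluation.
#' @param tol convergence tolerance on the hit fraction.
#' @return The scalar intensity calibration constant.
#' @export
calibrateCatastropheIntensity <- function(occupiedMask, thomas = thomasParams(),
                                          pCat = 0.14, nGen = 200,
                                          tol = 0.005) {
  if (pCat <= 0) return(0)
  nOcc <- sum(occupiedMask)
  stopifnot(nOcc > 0)
  hitFrac <- function(scale) {
    hits <- vapply(seq_len(nGen), function(i) {
      length(sampleCatastropheCells(occupiedMask, thomas, scale))
    }, 0L)
    mean(hits) / nOcc
  }
  lo <- 1e-3; hi <- 1
  while (hitFrac(hi) < pCat && hi < 1e6) hi <- hi * 4
  for (it in seq_len(30)) {
    mid <- sqrt(lo * hi)
    f <- hitFrac(mid)
    if (abs(f - pCat) < tol) return(mid)
    if (f < pCat) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Apply catastrophic mortality to struck cells
#'
#' Each struck cell loses an independently beta-drawn proportion of its
#' population with mean `mCat` and SD `mCat / 10`.
#'
#' @param N numeric matrix of abundances.
#' @param cells integer vector of struck cell indices.
#' @param mCat mean catastrophe mortality proportion.
#' @param round stochastically round survivors to integers.
#' @return Updated abundance matrix.
#' @export
applyCatastrophes <- function(N, cells, mCat = 0.5, round = TRUE) {
  if (!length(cells)) return(N)
  loss <- rbetaMoment(length(cells), mCat, mCat / 10)
  surv <- N[cells] * (1 - loss)
  N[cells] <- if (round) stochasticRound(surv) else surv
  N
}
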