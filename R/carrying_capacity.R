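# Carrying-capacity transforms of net primary production (NPP). All three
# relationships are defined over the *whole* stack of time slices: the NPP
# min-max normalization and the total-K matching are global (all land cells,
# all layers), so that the three relationships distribute the same overall
# number of people differently across space and time.

# Normalize a stack: list(npp matrices), list(land masks) -> common helpers.
stackValues <- function(nppStack, maskStack) {
  unlist(mapply(function(p, m) p[m], nppStack, maskStack, SIMPLIFY = FALSE),
         use.names = FALSE)
}

asStack <- function(x) if (is.matrix(x)) list(x) else x

checkNppStack <- function(nppStack, maskStack) {
  vals <- stackValues(nppStack, maskStack)
  if (length(unique(vals)) < 2)
    stop("NPP is constant over land; the min-max rescale is undefined")
  range(vals)
}

#' Linear carrying-capacity transform
#'
#' Min-max rescales NPP (over all land cells of all supplied slices) onto the
#' minimum--maximum hunter-gatherer density bounds and multiplies by cell
#' area, giving people per cell. Sea cells get K = 0.
#'
#' @param npp an NPP matrix or list of matrices (one per time slice).
#' @param landMask logical matrix or list of matrices matching `npp`.
#' @param bounds a [densityBounds()] list.
#' @return A K matrix, or list of K matrices when `npp` is a list.
#' @examples
#' npp <- matrix(c(0.1, 0.5, 1.0, 1.4), 2, 2)
#' kLinear(npp, matrix(TRUE, 2, 2))[1, 1] # 0.018 * 3080.25
#' @export
kLinear <- function(npp, landMask, bounds = densityBounds()) {
  single <- is.matrix(npp)
  nppS <- asStack(npp); maskS <- asStack(landMask)
  rng <- checkNppStack(nppS, maskS)
  out <- mapply(function(p, m) {
    dens <- bounds$dMin + (p - rng[1]) / (rng[2] - rng[1]) * (bounds$dMax - bounds$dMin)
    K <- dens * bounds$cellAreaKm2
    K[!m] <- 0
    K
  }, nppS, maskS, SIMPLIFY = FALSE)
  if (single) out[[1]] else out
}

#' Rotated-parabola carrying-capacity transform
#'
#' NPP is min-max normalized to \[0, 1\] (globally over the stack); on that
#' scale K follows the downward parabola `a * (p - h)^2 + Kmax` with
#' `a = -3`, `h` the median normalized NPP and peak `Kmax` at half the
#' linear relationship's maximum; negative values are clamped to zero.
#' The whole stack is finally rescaled so its total K (all cells, all
#' layers) equals the linear transform's total.
#'
#' @inheritParams kLinear
#' @param aPar parabola curvature on the normalized scale.
#' @param kMaxFrac peak height as a fraction of the linear maximum K.
#' @return A K matrix or list of K matrices.
#' @export
kParabolic <- function(npp, landMask, bounds = densityBounds(),
                       aPar = -3, kMaxFrac = 0.5) {
  single <- is.matrix(npp)
  nppS <- asStack(npp); maskS <- asStack(landMask)
  rng <- checkNppStack(nppS, maskS)
  h <- median((stackValues(nppS, maskS) - rng[1]) / (rng[2] - rng[1]))
  kMaxLin <- bounds$dMax * bounds$cellAreaKm2
  raw <- mapply(function(p, m) {
    pn <- (p - rng[1]) / (rng[2] - rng[1])
    K <- (aPar * (pn - h)^2 + kMaxFrac) * kMaxLin
    K[K < 0] <- 0
    K[!m] <- 0
    K
  }, nppS, maskS, SIMPLIFY = FALSE)
  out <- matchTotalK(raw, kLinear(nppS, maskS, bounds))
  if (single) out[[1]] else out
}

#' Reciprocal quadratic-yield-density carrying-capacity transform
#'
#' Applies the unimodal curve `K = P / (a + b P + c P^2)` with `a = 200`,
#' `b = 0.6`, `c = 0.2`, whose maximum sits at `P* = sqrt(a / c)`. Normalized
#' NPP in \[0, 1\] is mapped linearly onto the working domain
#' \[0, 2 sqrt(a/c)\] so that mid-range NPP hits the peak; the stack is then
#' rescaled so its total K equals the linear transform's total.
#'
#' @inheritParams kLinear
#' @param aQ,bQ,cQ curve coefficients.
#' @return A K matrix or list of K matrices.
#' @export
kQyd <- function(npp, landMask, bounds = densityBounds(),
                 aQ = 200, bQ = 0.6, cQ = 0.2) {
  single <- is.matrix(npp)
  nppS <- asStack(npp); maskS <- asStack(landMask)
  rng <- checkNppStack(nppS, maskS)
  domMax <- 2 * sqrt(aQ / cQ)
  raw <- mapply(function(p, m) {
    P <- (p - rng[1]) / (rng[2] - rng[1]) * domMax
    K <- qydCurve(P, aQ, bQ, cQ)
    K[!m] <- 0
    K
  }, nppS, maskS, SIMPLIFY = FALSE)
  out <- matchTotalK(raw, kLinear(nppS, maskS, bounds))
  if (single) out[[1]] else out
}

#' Reciprocal quadratic-yield-density curve
#'
#' @param P productivity on the working domain.
#' @param aQ,bQ,cQ coefficients.
#' @return `P / (aQ + bQ * P + cQ * P^2)`.
#' @export
qydCurve <- function(P, aQ = 200, bQ = 0.6, cQ = 0.2) {
  P / (aQ + bQ * P + cQ * P^2)
}

# Rescale a K stack so its grand total matches a reference stack's total.
matchTotalK <- function(stack, refStack) {
  tot <- sum(vapply(stack, sum, 0))
  ref <- sum(vapply(refStack, sum, 0))
  if (tot <= 0) stop("degenerate K stack: total K is zero")
  lapply(stack, function(K) K * ref / tot)
}

#' Carrying-capacity stack for a landscape
#'
#' Applies the chosen K--NPP relationship to every time slice of a
#' [PaleoLandscape-class].
#'
#' @param landscape a [PaleoLandscape-class].
#' @param model `"linear"`, `"parabolic"` or `"qyd"`.
#' @param bounds a [densityBounds()] list.
#' @return List of K matrices, one per slice (people per cell).
#' @export
computeKStack <- function(landscape, model = c("linear", "parabolic", "qyd"),
                          bounds = densityBounds()) {
  model <- match.arg(model)
  f <- switch(model, linear = kLinear, parabolic = kParabolic, qyd = kQyd)
  f(landscape@npp, landscape@landMask, bounds)
}

#' Poisson resampling of a K grid
#'
#' Replaces each land cell's K by a Poisson draw with that mean, emulating
#' spatio-temporal uncertainty in carrying capacity; sea cells stay at zero.
#'
#' @param K numeric matrix (people per cell).
#' @param landMask logical matrix.
#' @return Integer-valued numeric matrix.
#' @export
resampleK <- function(K, landMask) {
  stopifnot(all(K >= 0))
  out <- matrix(0, nrow(K), ncol(K))
  idx <- which(landMask & K > 0)
  out[idx] <- rpois(length(idx), K[idx])
  out
}
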