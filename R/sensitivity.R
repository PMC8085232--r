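# Global sensitivity analysis: Latin-hypercube sampling of twelve model
# parameters, time-to-saturation responses, and a boosted-regression-tree
# emulator yielding relative-influence scores.

#' Default twelve-parameter sensitivity space
#'
#' Uniform sampling ranges for the twelve parameters varied in the global
#' sensitivity analysis (roughly +/-50% around each default, with explicit
#' caps where a proportion may not exceed 0.99).
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
parameterSpace <- function() {
  data.frame(
    name = c("rMax", "dMaxKm", "dCellMult", "nMVP", "mMVP", "omega",
             "mCat", "pMig", "fissionLo", "fissionHi", "R", "nFirst"),
    lower = c(0.10, 11, 1, 50, 0.1, 1.5, 0.38, 0.17, 0.15, 0.35, 0.5, 50),
    upper = c(0.31, 34, 5, 150, 0.3, 4.5, 0.99, 0.50, 0.45, 0.99, 1.5, 150),
    stringsAsFactors = FALSE
  )
}

#' Latin-hypercube sample of a parameter space
#'
#' Draws `n` rows such that, for every parameter, exactly one value falls in
#' each of the `n` equal-probability strata of its range.
#'
#' @param space data.frame with `name`, `lower`, `upper` (see
#'   [parameterSpace()]).
#' @param n number of design rows (>= 2).
#' @return data.frame of sampled parameter values, one column per parameter.
#' @export
latinHypercube <- function(space = parameterSpace(), n = 1000) {
  stopifnot(n >= 2, all(space$lower < space$upper))
  u <- lhs::randomLHS(n, nrow(space))
  out <- as.data.frame(sweep(sweep(u, 2, space$upper - space$lower, "*"),
                             2, space$lower, "+"))
  names(out) <- space$name
  out
}

#' Run the sensitivity design through the simulator
#'
#' One single-iteration simulation per design row on the supplied landscape,
#' under the base scenario settings (by default a 50-ka single southern
#' entry with the rotated-parabolic K relationship). Rows whose fission
#' bounds arrive inverted (the two ranges overlap) are reordered. The
#' response is the time to continental saturation in years; runs that do not
#' saturate within the horizon are flagged censored, with the horizon as a
#' lower bound, and keep `NA` as the response.
#'
#' @param design data.frame from [latinHypercube()].
#' @param landscape a [PaleoLandscape-class].
#' @param entryCells named entry-cell list (see [runScenario()]).
#' @param baseScenario the fixed [Scenario-class] settings.
#' @param seed master seed; row seeds are derived from it.
#' @param horizon generations per run.
#' @return `design` with added columns `responseYears`, `censored` and
#'   `saturationGeneration`.
#' @export
runDesign <- function(design, landscape, entryCells,
                      baseScenario = scenario(50, "S", "parabolic"),
                      seed = 1, horizon = 300) {
  stopifnot(nrow(design) >= 1)
  set.seed(seed)
  rowSeeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
  demog0 <- demographyParams()
  # catastrophe placement calibration does not involve the sampled
  # parameters, so calibrate once against the entry-age land mask
  d <- dim(landscape@grid)
  mask0 <- landMaskAt(landscape, baseScenario@entryAgeKa * 1000)
  ref <- matrix(FALSE, d[1], d[2])
  landIdx <- which(mask0)
  set.seed(seed)
  ref[sample(landIdx, max(1, length(landIdx) %/% 2))] <- TRUE
  catScale <- calibrateCatastropheIntensity(ref, thomasParams(), demog0$pCat)

  res <- lapply(seq_len(nrow(design)), function(i) {
    p <- design[i, ]
    flo <- min(p$fissionLo, p$fissionHi)
    fhi <- max(p$fissionLo, p$fissionHi)
    demog <- demographyParams(rMax = p$rMax, nMVP = p$nMVP, mMVP = p$mMVP,
                              mCat = p$mCat)
    disp <- dispersalParams(pMig = p$pMig, fissionLo = flo, fissionHi = fhi,
                            dMaxKm = p$dMaxKm, dCellMult = p$dCellMult,
                            omega = p$omega, R = p$R)
    ens <- runScenario(baseScenario, landscape, entryCells, demog, disp,
                       nIter = 1, seed = rowSeeds[i], horizon = horizon,
                       nFirst = p$nFirst, catIntensityScale = catScale)
    ens@saturationGeneration[1]
  })
  satGen <- unlist(res)
  design$saturationGeneration <- satGen
  design$censored <- is.na(satGen)
  design$responseYears <- satGen * demog0$generationYears
  design
}

#' Boosted-regression-tree emulator and relative influence
#'
#' Fits a gradient-boosted tree emulator of the response over the sampled
#' parameters (Gaussian loss, depth-2 trees for first-order interactions,
#' bag fraction 0.75, learning rate 0.008, up to 10,000 trees with early
#' stopping once the training deviance improvement falls below `tolerance`)
#' and reports each parameter's relative influence, normalized to sum to
#' 100, plus the proportion of deviance explained. Rows with non-finite
#' responses are excluded with a warning.
#'
#' @param design data.frame of parameter columns.
#' @param response numeric response vector (e.g. years to saturation).
#' @param nTrees maximum number of boosting rounds.
#' @param learningRate shrinkage per round.
#' @param bagFraction row subsampling fraction per round.
#' @param treeComplexity maximum tree depth.
#' @param tolerance minimum training-RMSE improvement to continue boosting.
#' @return List with `influence` (named vector summing to 100),
#'   `devianceExplained`, `nTreesUsed` and the fitted `model`.
#' @export
emulateInfluence <- function(design, response, nTrees = 10000,
                             learningRate = 0.008, bagFraction = 0.75,
                             treeComplexity = 2, tolerance = 1e-4) {
  keep <- is.finite(response)
  if (any(!keep)) {
    warning(sum(!keep), " rows with non-finite responses excluded")
    design <- design[keep, , drop = FALSE]
    response <- response[keep]
  }
  stopifnot(nrow(design) >= 10)
  X <- as.matrix(design)
  dtrain <- xgboost::xgb.DMatrix(X, label = response)
  params <- list(objective = "reg:squarederror", eta = learningRate,
                 max_depth = treeComplexity, subsample = bagFraction,
                 nthread = 1)
  # boost in chunks, stopping once the training-RMSE improvement per chunk
  # drops below the tolerance (the R interface exposes no min-delta stop)
  chunk <- 250L
  model <- NULL
  prevRMSE <- Inf
  used <- 0L
  while (used < nTrees) {
    nr <- min(chunk, nTrees - used)
    model <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nr,
                                xgb_model = model, verbose = 0)
    used <- used + nr
    rmse <- sqrt(mean((response - predict(model, X))^2))
    if (prevRMSE - rmse < tolerance) break
    prevRMSE <- rmse
  }
  pred <- predict(model, X)
  dev <- 1 - mean((response - pred)^2) / mean((response - mean(response))^2)
  imp <- xgboost::xgb.importance(model = model)
  infl <- setNames(rep(0, ncol(design)), colnames(design))
  infl[imp$Feature] <- imp$Gain
  infl <- infl / sum(infl) * 100
  list(influence = infl, devianceExplained = dev,
       nTreesUsed = used, model = model)
}
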