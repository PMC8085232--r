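test_that("the default factor grid enumerates all 120 scenarios", {
  grid <- buildScenarioGrid()
  expect_length(grid, 120)
  ids <- vapply(grid, scenarioId, "")
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(buildScenarioGrid(50, "S", "linear"), 1)
  expect_error(buildScenarioGrid(entryAgesKa = numeric(0)), "at least one")
  expect_error(buildScenarioGrid(kModels = c("linear", "linear")), "duplicate")
})

test_that("entry seeding draws founders within bounds and rejects drowned cells", {
  spec <- gridSpec(4, 4, latMin = -12, latMax = -10, lonMin = 120, lonMax = 122)
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  set.seed(20)
  founders <- replicate(300, {
    st <- seedEntry(emptyState(spec), c(2, 2), c(1300, 1500), mask)
    st@N[2, 2]
  })
  expect_true(all(founders >= 1300 & founders <= 1500))
  expect_gt(diff(range(founders)), 50) # actually stochastic
  expect_error(seedEntry(emptyState(spec), c(1, 1), c(1300, 1500), mask, 50000),
               "under water")
})

test_that("staged sequences schedule the second entry 72 generations later", {
  cells <- list(S = c(2, 2), N = c(3, 3))
  sched <- paleospread:::scheduleEntries(scenario(50, "S-N"), cells)
  expect_equal(sched$generation, c(0L, 72L))
  expect_equal(unlist(sched[1, c("row", "col")], use.names = FALSE), c(2, 2))
  sched2 <- paleospread:::scheduleEntries(scenario(50, "N-S"), cells)
  expect_equal(sched2$generation, c(0L, 72L))
  expect_equal(unlist(sched2[1, c("row", "col")], use.names = FALSE), c(3, 3))
  expect_equal(paleospread:::scheduleEntries(scenario(50, "SN"), cells)$generation,
               c(0L, 0L))
  expect_error(paleospread:::scheduleEntries(scenario(50, "S-N"), list(S = c(1, 1))),
               "entry cell")
})

test_that("an empty grid is absorbing under the generation update", {
  strip <- stripLandscape()
  kStack <- computeKStack(strip, "linear")
  st <- emptyState(strip@grid)
  set.seed(21)
  for (t in 1:5) st <- runGeneration(st, strip, kStack, 55000)
  expect_equal(sum(st@N), 0)
  expect_true(all(is.na(st@firstArrival)))
})

test_that("fixed master seeds reproduce ensembles bit-identically", {
  strip <- stripLandscape()
  scn <- scenario(50, "S", "linear")
  run <- function() runScenario(scn, strip, list(S = c(3, 2)), nIter = 2,
                                seed = 77, horizon = 30,
                                calibrateCatastrophes = FALSE)
  e1 <- run(); e2 <- run()
  expect_identical(e1@meanArrival, e2@meanArrival)
  expect_identical(e1@trajectories, e2@trajectories)
  # single-iteration percentile maps collapse onto the mean map
  e3 <- runScenario(scn, strip, list(S = c(3, 2)), nIter = 1, seed = 5,
                    horizon = 30, calibrateCatastrophes = FALSE)
  expect_equal(e3@loArrival, e3@meanArrival)
  expect_equal(e3@hiArrival, e3@meanArrival)
})

test_that("without dispersal or catastrophes a lone cell settles near carrying capacity", {
  strip <- stripLandscape()
  kStack <- computeKStack(strip, "linear")
  demog <- demographyParams(pCat = 0)
  disp <- dispersalParams(pMig = 0)
  st <- emptyState(strip@grid)
  st@N[3, 15] <- 500
  kTrue <- kStack[[1]][3, 15]
  set.seed(22)
  traj <- numeric(250)
  for (t in 1:250) {
    st <- runGeneration(st, strip, kStack, 60000 - t * 27.9, demog, disp,
                        catIntensityScale = 0)
    traj[t] <- st@N[3, 15]
  }
  expect_lt(abs(mean(traj[101:250]) - kTrue) / kTrue, 0.1)
  expect_equal(sum(st@N) - st@N[3, 15], 0) # nobody left the cell
})

test_that("arrival sweeps outward: nearer cells are reached earlier on a homogeneous strip", {
  strip <- stripLandscape()
  ens <- runScenario(scenario(58, "S", "linear"), strip, list(S = c(3, 2)),
                     nIter = 4, seed = 30, horizon = 120,
                     calibrateCatastrophes = FALSE)
  arr <- ens@meanArrival
  colArr <- colMeans(arr, na.rm = TRUE)
  reached <- which(!is.nan(colArr))
  expect_gt(length(reached), 15)
  dist <- abs(reached - 2)
  expect_gt(cor(dist, colArr[reached], method = "spearman"), 0.9)
  # travelling wave: front position grows roughly linearly with time
  fit <- lm(colArr[reached] ~ dist)
  expect_gt(summary(fit)$r.squared, 0.85)
})

test_that("saturation metrics convert generations to years and front rates", {
  strip <- stripLandscape()
  scn <- scenario(50, "S", "linear")
  ens <- new("EnsembleResult",
    meanArrival = matrix(0, 5, 30), loArrival = matrix(0, 5, 30),
    hiArrival = matrix(0, 5, 30), trajectories = matrix(0, 10, 3),
    saturationGeneration = c(156, 208, NA), nIter = 3L, nFirst = 100,
    scenario = scn)
  m <- saturationMetrics(ens, c(3, 2), c(3, 30), strip@grid, 28.0)
  expect_equal(m$generations, c(156, 208))
  expect_equal(m$years, c(156, 208) * 28.0)
  expect_equal(m$rateKmPerYear,
               rev(m$distanceKm / m$years))
  # doubling the generation length doubles years and halves the rate
  m2 <- saturationMetrics(ens, c(3, 2), c(3, 30), strip@grid, 56.0)
  expect_equal(m2$years, 2 * m$years)
  expect_equal(m2$rateKmPerYear, m$rateKmPerYear / 2)
  # same-cell reference: zero distance, zero rate
  m0 <- saturationMetrics(ens, c(3, 2), c(3, 2), strip@grid)
  expect_equal(m0$rateKmPerYear, c(0, 0))
  # never saturated: unset, not an error
  ens@saturationGeneration <- rep(NA_real_, 3)
  mNA <- saturationMetrics(ens, c(3, 2), c(3, 30), strip@grid)
  expect_true(all(is.na(mNA$generations)))
})

test_that("drowned occupants relocate to the nearest land instead of persisting at sea", {
  N <- matrix(0, 4, 4)
  N[1, 1] <- 250
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  out <- paleospread:::relocateDrowned(N, mask)
  expect_equal(sum(out), 250)
  expect_equal(out[1, 1], 0)
  expect_true(out[1, 2] == 250 || out[2, 1] == 250 || out[2, 2] == 250)
  # fully drowned world: the population is lost
  allSea <- matrix(FALSE, 4, 4)
  expect_equal(sum(paleospread:::relocateDrowned(N, allSea)), 0)
})
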