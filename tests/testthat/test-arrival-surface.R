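test_that("the Solow terminal estimator matches its closed form", {
  expect_equal(solowTerminal(c(10, 20, 30), 0), 40)        # (4/3) * 30
  expect_equal(solowTerminal(7, 0), 14)                    # n = 1: A0 + 2(a - A0)
  expect_equal(solowTerminal(c(35000, 38000), 30000),
               30000 + (3 / 2) * 8000)
  # large n with fixed maximum: correction vanishes
  expect_equal(solowTerminal(c(rep(10, 9999), 30), 0), 30, tolerance = 1e-3)
  expect_error(solowTerminal(c(5, 20), 10), "A0")
})

test_that("variogram models have zero semivariance at the origin and vanishing covariance afar", {
  m <- fixedVariogram(psill = 4, range = 100, nugget = 1)
  expect_equal(variogramValue(m, 0), 0)
  expect_equal(variogramValue(m, 1e-9), 1, tolerance = 1e-6) # nugget limit
  expect_equal(covarianceValue(m, 1e9), 0, tolerance = 1e-6)
  expect_true(all(diff(variogramValue(m, seq(1, 1000, by = 10))) >= 0))
})

test_that("constant ages give a near-zero empirical variogram", {
  rec <- scatterRecords(20)
  rec$age_bp <- 40000
  vm <- fitVariogram(rec)
  expect_lt(max(vm@empirical$gamma), 1e-9)
  expect_lt(vm@psill, 1e-6)
})

test_that("variogram fitting recovers the range and sill of a known random field", {
  rec <- simulateGRF(n = 200, sill = 1e6, range = 300, seed = 41)
  vm <- fitVariogram(rec)
  expect_lt(abs(vm@rangeParam - 300) / 300, 0.25)
  # fitted total sill is on the scale of the sample variance of the ages
  expect_lt(abs((vm@nugget + vm@psill) - var(rec$age_bp)) / var(rec$age_bp), 0.5)
  expect_lt(vm@nugget / (vm@nugget + vm@psill), 0.25) # field has no nugget
})

test_that("ordinary kriging interpolates exactly, honours constants, and splits symmetric pairs", {
  rec <- scatterRecords(20)
  m <- fixedVariogram(psill = var(rec$age_bp), range = 400)
  # zero nugget: exact interpolation at a record location
  expect_equal(krigeAge(rec, m, cbind(rec$lon[3], rec$lat[3])), rec$age_bp[3])
  # constant ages reproduce the constant everywhere (weights sum to one)
  recc <- rec; recc$age_bp <- 41000
  expect_equal(krigeAge(recc, m, cbind(131.2, -22.7)), 41000)
  # two symmetric records: equal weights of one half
  r2 <- data.frame(lon = c(129, 131), lat = c(-20, -20),
                   age_bp = c(35000, 45000))
  w <- krigeAge(r2, m, cbind(130, -20), returnWeights = TRUE)
  expect_equal(as.vector(w$weights), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(w$predictions, 40000, tolerance = 1e-6)
})

test_that("the preliminary surface doubles the kriged mean above the reference age", {
  spec <- smallGrid(12, 12)
  mask <- matrix(TRUE, 12, 12)
  rec <- scatterRecords(15)
  m <- fixedVariogram(psill = var(rec$age_bp), range = 400)
  # M = A0 everywhere -> Ap = A0
  recc <- rec; recc$age_bp <- 30000
  ap <- preliminarySurface(recc, m, spec, mask, A0 = 30000)
  expect_equal(unique(round(as.vector(ap), 6)), 30000)
  # uniform deposition on [A0, A]: E[Ap] ~ A (law-of-large-numbers check)
  set.seed(42)
  A <- 48000; A0 <- 30000
  recu <- scatterRecords(120, seed = 43)
  recu$age_bp <- runif(120, A0, A)
  vm <- fitVariogram(recu)
  apu <- preliminarySurface(recu, vm, spec, mask, A0)
  expect_lt(abs(mean(apu) - A) / (A - A0), 0.12)
})

test_that("bias correction is consistent when dating error is degenerate and rejects k < 2", {
  spec <- smallGrid(10, 10)
  mask <- matrix(TRUE, 10, 10)
  rec <- scatterRecords(25, seed = 44)
  rec$sd <- 0
  expect_error(biasCorrectedSurface(rec, spec, mask, k = 1), "k")
  set.seed(1)
  s1 <- biasCorrectedSurface(rec, spec, mask, k = 10, useSigma = TRUE)
  set.seed(1)
  s2 <- biasCorrectedSurface(rec, spec, mask, k = 10, useSigma = FALSE)
  expect_equal(arrivalEstimate(s1), arrivalEstimate(s2))
  expect_true(all(arrivalEstimate(s1) >= s1@A0 - 1e-9, na.rm = TRUE))
})

test_that("removing one record perturbs the kriged surface most near that record", {
  spec <- smallGrid(15, 15)
  mask <- matrix(TRUE, 15, 15)
  rec <- scatterRecords(20, seed = 45)
  vm <- fixedVariogram(psill = var(rec$age_bp), range = 300)
  full <- paleospread:::krigeGrid(rec, vm, spec, mask)
  cc <- cellCentres(spec)
  drop <- 7
  loo <- paleospread:::krigeGrid(rec[-drop, ], vm, spec, mask)
  delta <- abs(full - loo)
  peak <- which(delta == max(delta), arr.ind = TRUE)[1, ]
  dPeak <- geosphere::distHaversine(
    c(cc$lon[peak[2]], cc$lat[peak[1]]),
    c(rec$lon[drop], rec$lat[drop])) / 1000
  # the largest change sits within a couple of cells of the removed record
  expect_lt(dPeak, 200)
})

test_that("record filtering honours quality allow-lists and site exclusions", {
  rec <- scatterRecords(10)
  rec$quality <- rep(c("A*", "A", "B"), length.out = 10)
  kept <- filterRecords(rec, allowQuality = c("A*", "A"))
  expect_true(all(kept$quality %in% c("A*", "A")))
  out <- filterRecords(rec, excludeSites = "s03")
  expect_false("s03" %in% out$site)
})

test_that("the bundled synthetic records CSV round-trips through the reader", {
  path <- system.file("extdata", "synthetic_dates.csv", package = "paleospread")
  rec <- readDatedRecords(path)
  expect_equal(nrow(rec), 40)
  expect_true(all(c("site", "lon", "lat", "age_bp", "sd", "quality") %in% names(rec)))
  expect_true(all(rec$age_bp >= 30000))
  bad <- tempfile(fileext = ".csv")
  write.csv(rec[, c("site", "lon")], bad, row.names = FALSE)
  expect_error(readDatedRecords(bad), "missing columns")
})
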