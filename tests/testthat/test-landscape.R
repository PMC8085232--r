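test_that("ruggedness index matches hand evaluation and degenerates on flat fields", {
  e <- matrix(0, 3, 3)
  e[2, 2] <- 10
  raw <- computeRuggedness(e, raw = TRUE)
  # centre: eight differences of 10 -> RMS = 10
  expect_equal(raw[2, 2], 10)
  # flat field standardizes to all zeros
  expect_equal(computeRuggedness(matrix(5, 4, 4)), matrix(0, 4, 4))
  expect_error(computeRuggedness(matrix(0, 2, 2)), "3")
})

test_that("interior cells of a monotone ramp share the same raw ruggedness", {
  ramp <- matrix(rep(seq(0, 90, by = 10), each = 8), 8, 10)
  raw <- computeRuggedness(ramp, raw = TRUE)
  interior <- raw[3:6, 3:8]
  # brute-force oracle at one interior cell: differences to 8 neighbours
  nb <- c(ramp[3, 3], ramp[2, 4], ramp[3, 5], ramp[2, 3], ramp[4, 3],
          ramp[2, 5], ramp[4, 5], ramp[4, 4]) - ramp[3, 4]
  expect_equal(unique(round(as.vector(interior), 12)),
               round(sqrt(mean(nb^2)), 12))
})

test_that("ruggedness is invariant to elevation offsets and spans [0, 1]", {
  set.seed(4)
  e <- matrix(rnorm(100, 0, 50), 10, 10)
  g1 <- computeRuggedness(e)
  g2 <- computeRuggedness(e + 1234)
  expect_equal(g1, g2)
  expect_equal(range(g1), c(0, 1))
})

test_that("time slices flood and expose cells at the sea-level threshold", {
  e <- matrix(c(-80, 10, 50, 200), 2, 2)
  series <- data.frame(age_bp = c(50000, 49000), level_m = c(-120, -60))
  ts <- buildTimeSlices(e, series, c(50000, 49000))
  # shelf cell at -80 m: land at sea level -120, sea at -60
  expect_true(ts$landMask[[1]][1, 1])
  expect_false(ts$landMask[[2]][1, 1])
  # positive-elevation cells are land in both
  expect_true(all(ts$landMask[[1]][-1]))
  # sea level above all elevation -> no land
  hi <- data.frame(age_bp = 50000, level_m = 500)
  expect_false(any(buildTimeSlices(e, hi, 50000)$landMask[[1]]))
  expect_error(buildTimeSlices(e, series, c(50000, 48000)), "48000")
})

test_that("lake basin cells are masked only while the lake floods them", {
  e <- matrix(10, 3, 3)
  basin <- matrix(FALSE, 3, 3); basin[2, 2] <- TRUE
  series <- data.frame(age_bp = c(50000, 49000), level_m = c(-120, -120))
  lake <- data.frame(age_bp = c(50000, 49000), level_m = c(20, 0))
  ts <- buildTimeSlices(e, series, c(50000, 49000), basin, lake)
  expect_false(ts$landMask[[1]][2, 2]) # flooded at lake level 20 m
  expect_true(ts$landMask[[2]][2, 2])  # dry at lake level 0 m
  expect_error(buildTimeSlices(e, series, c(50000, 49000), basin), "lakeLevel")
})

test_that("land area never grows as sea level rises over a fixed relief", {
  set.seed(9)
  e <- matrix(rnorm(400, 0, 80), 20, 20)
  levels <- seq(-120, 60, by = 20)
  areas <- vapply(levels, function(l) {
    s <- data.frame(age_bp = 50000, level_m = l)
    sum(buildTimeSlices(e, s, 50000)$landMask[[1]])
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("bilinear downscaling preserves constants, nodes and a 1-D oracle", {
  spec <- gridSpec(8, 8, latMin = -20, latMax = -12, lonMin = 120, lonMax = 128)
  cl <- c(-11, -16, -21); cn <- c(119, 124, 129)
  # constant field stays constant
  const <- downscaleBilinear(matrix(7, 3, 3), cl, cn, spec)
  expect_equal(const, matrix(7, 8, 8))
  # 2x2 corners (0, 0, 1, 1): midpoint is 0.5
  spec1 <- gridSpec(2, 2, latMin = -17, latMax = -15, lonMin = 121, lonMax = 123)
  coarse <- matrix(c(0, 0, 1, 1), 2, 2) # columns west(0), east(1)
  fine <- downscaleBilinear(coarse, c(-15, -17), c(121, 123), spec1)
  expect_equal(mean(fine), 0.5)
  # random 3x3 against an independent two-pass 1-D interpolation oracle
  set.seed(1)
  z <- matrix(rnorm(9), 3, 3)
  got <- downscaleBilinear(z, cl, cn, spec)
  cc <- cellCentres(spec)
  oracle <- matrix(NA_real_, 8, 8)
  for (i in 1:8) {
    rowVals <- vapply(1:3, function(k) {
      approx(rev(cl), rev(z[, k]), xout = cc$lat[i])$y
    }, 0)
    oracle[i, ] <- approx(cn, rowVals, xout = cc$lon)$y
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("between-slice interpolation is exact on slices, linear between, and bracketed", {
  strip <- stripLandscape()
  strip@npp[[2]] <- strip@npp[[1]] * 2
  onSlice <- interpolateGenerations(strip, 60000)
  expect_equal(onSlice$npp, strip@npp[[1]])
  mid <- interpolateGenerations(strip, mean(strip@ages))
  expect_equal(mid$npp, 1.5 * strip@npp[[1]])
  # generic bracketing property at random ages
  set.seed(2)
  for (age in runif(5, 35000, 60000)) {
    v <- interpolateGenerations(strip, age)$npp
    expect_true(all(v >= pmin(strip@npp[[1]], strip@npp[[2]]) - 1e-12))
    expect_true(all(v <= pmax(strip@npp[[1]], strip@npp[[2]]) + 1e-12))
  }
  expect_error(interpolateGenerations(strip, 70000), "span")
})

test_that("distance-to-water is zero on wet cells and grows with separation", {
  wet <- matrix(FALSE, 5, 7); wet[3, 2] <- TRUE
  d <- distanceToWater(wet)
  expect_equal(d[3, 2], 0)
  expect_equal(d[3, 5], 3)
  expect_equal(d[1, 2], 2)
  expect_equal(d[1, 1], sqrt(5))
  expect_true(all(is.infinite(distanceToWater(matrix(FALSE, 2, 2)))))
})
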