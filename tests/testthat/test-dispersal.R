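test_that("emigration probability follows the exponential gradient law", {
  expect_equal(emigrationProbability(0), 1)
  expect_equal(emigrationProbability(1), exp(-3.2), tolerance = 1e-12)
  k <- seq(0, 1, by = 0.1)
  expect_true(all(diff(emigrationProbability(k)) < 0))
})

test_that("allometric dispersal distance reproduces the published corner values", {
  expect_equal(round(allometricMaxDistance(50, 3.31 - 1.17, 0.65 - 0.05), 1), 22.4)
  expect_equal(round(allometricMaxDistance(50, 3.31 + 1.17, 0.65 + 0.05), 1), 69.3)
  expect_equal(round(allometricMaxDistance(50), 1), 42.1)
  expect_error(allometricMaxDistance(-1), "positive")
})

test_that("mobility areas convert to the published circular radii", {
  expect_equal(round(mobilityRadius(c(1400, 3900, 2600)), 1),
               c(21.1, 35.2, 28.8))
  expect_equal(mobilityRadius(0), 0)
})

test_that("water limitation vanishes at water, saturates at the dispersal range, and caps as a barrier", {
  expect_equal(waterLimitedProbability(1, 0, 3), 1)   # water in the cell
  expect_equal(waterLimitedProbability(1, 1, 3), 0)   # boundary
  expect_equal(waterLimitedProbability(2, 1, 3), 0.875)
  # default (inverted) form: anywhere drier than the dispersal range is a barrier
  expect_equal(waterLimitedProbability(2, 3, 4), 0)
  # literal printed form with a huge exponent: full barrier when D_H2O < D_l
  expect_equal(waterLimitedProbability(2, 1, 500, literal = TRUE), 0)
})

test_that("ruggedness reduces movement by at most ~1% at default coefficients", {
  expect_equal(ruggednessFactor(0), 1) # clamped from 1.001116
  expect_equal(ruggednessFactor(1), 1.001116 - 0.0104453, tolerance = 1e-9)
  expect_lt(1 - ruggednessFactor(1), 0.01)
  # the resistance modifier scales the reduction linearly
  expect_equal(1 - ruggednessFactor(1, R = 2), 2 * (1 - ruggednessFactor(1)),
               tolerance = 1e-12)
})

test_that("long-distance displacement scale inflates 12.7-fold per NPP decade and respects the cap", {
  set.seed(8)
  drawMag <- function(nppRel, cap = 1e6) {
    mean(replicate(4000, {
      d <- sampleLddDistance(40, nppRel, cellWidthKm = 55.6, dCellMax = cap)
      abs(d[1])
    }))
  }
  m1 <- drawMag(1); m01 <- drawMag(0.1)
  expect_equal(m01 / m1, 12.7, tolerance = 0.15)
  # signs are randomized
  set.seed(9)
  ds <- replicate(500, sampleLddDistance(200, 1)[1])
  expect_true(any(ds > 0) && any(ds < 0))
  # a tight cap keeps displacements within a few cells
  set.seed(10)
  capped <- replicate(1000, max(abs(sampleLddDistance(1e4, 0.01, dCellMax = 1))))
  expect_lt(mean(capped), 4) # Exp(mean 1 cell) then Poisson: mostly 0-3 cells
})

test_that("both movement passes conserve people exactly over random configurations", {
  set.seed(11)
  for (rep in 1:15) {
    nr <- sample(4:8, 1); nc <- sample(4:9, 1)
    land <- matrix(runif(nr * nc) < 0.8, nr, nc)
    K <- matrix(0, nr, nc); K[land] <- runif(sum(land), 50, 3000)
    N <- matrix(0, nr, nc); N[land] <- rpois(sum(land), 400)
    rug <- matrix(runif(nr * nc), nr, nc)
    dw <- matrix(runif(nr * nc, 0, 4), nr, nc)
    nppRel <- matrix(runif(nr * nc, 0.05, 1), nr, nc)
    n1 <- neighbourExchange(N, K, rug)
    expect_equal(sum(n1), sum(N))
    expect_true(all(n1 >= 0))
    n2 <- longDistanceDispersal(N, K, land, dw, nppRel, rug)
    expect_equal(sum(n2), sum(N))
    expect_true(all(n2 >= 0))
  }
})

test_that("a saturated source next to an empty better cell sends about a third of its people", {
  # focal (2,2) with tiny K (forced fission, Krel ~ 0 -> certain emigration);
  # the single better neighbour sits NW so the first direction fires
  K <- matrix(0, 3, 3); K[2, 2] <- 1; K[1, 1] <- 1e6
  rug <- matrix(0, 3, 3)
  set.seed(12)
  moved <- replicate(400, {
    N <- matrix(0, 3, 3); N[2, 2] <- 300
    out <- neighbourExchange(N, K, rug)
    out[1, 1]
  })
  expect_equal(mean(moved), 100, tolerance = 0.03)
})

test_that("uniform K at carrying capacity produces no neighbour flow", {
  K <- matrix(500, 4, 4)
  N <- matrix(500, 4, 4)
  set.seed(13)
  out <- neighbourExchange(N, K, matrix(0, 4, 4))
  expect_equal(out, N) # Krel = 1 never passes the strict < 1 gate
})

test_that("zero migrating proportion freezes the spatial distribution", {
  set.seed(14)
  K <- matrix(runif(36, 100, 2000), 6, 6)
  N <- matrix(rpois(36, 300), 6, 6)
  p0 <- dispersalParams(pMig = 0)
  expect_equal(neighbourExchange(N, K, matrix(0.5, 6, 6), p0), N)
  land <- matrix(TRUE, 6, 6)
  expect_equal(longDistanceDispersal(N, K, land, matrix(0, 6, 6),
                                     matrix(1, 6, 6), matrix(0, 6, 6), p0), N)
})

test_that("net neighbour flow climbs the carrying-capacity gradient", {
  # two occupied cells side by side; people should accumulate in the high-K cell
  K <- matrix(c(200, 800), 1, 2)
  set.seed(15)
  gain <- replicate(300, {
    N <- matrix(c(200, 800), 1, 2)
    out <- neighbourExchange(N, K, matrix(0, 1, 2))
    out[1, 2] - 800
  })
  expect_gt(mean(gain), 0)
})

test_that("long-distance targets on sea or off-grid move nobody", {
  # single land cell in an ocean: every LDD target is sea, population fixed
  land <- matrix(FALSE, 5, 5); land[3, 3] <- TRUE
  K <- matrix(0, 5, 5); K[3, 3] <- 10
  N <- matrix(0, 5, 5); N[3, 3] <- 500
  set.seed(16)
  for (i in 1:20) {
    out <- longDistanceDispersal(N, K, land, matrix(0, 5, 5),
                                 matrix(1, 5, 5), matrix(0, 5, 5))
    expect_equal(out, N)
  }
})
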