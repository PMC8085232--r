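test_that("Ricker growth has its fixed point at K and matches direct evaluation", {
  # N = K is an exact fixed point (integer abundances survive rounding)
  N <- matrix(c(100, 0), 1, 2); K <- matrix(100, 1, 2)
  expect_equal(rickerGrowth(N, K, 0.3), N)
  # N = 50, K = 100, r = 0.2 -> 50 * exp(0.1) expected
  expect_equal(rickerGrowth(matrix(50), matrix(100), 0.2, round = FALSE)[1, 1],
               50 * exp(0.1))
  # stochastic rounding preserves the expectation
  set.seed(1)
  draws <- replicate(800, rickerGrowth(matrix(50), matrix(100), 0.2)[1, 1])
  expect_lt(abs(mean(draws) - 50 * exp(0.1)), 0.1)
  # K = 0 cells are left for the relocation step, not exploded
  expect_equal(rickerGrowth(matrix(10), matrix(0), 0.2), matrix(10))
})

test_that("the MVP penalty strikes only small populations at the configured mean", {
  expect_equal(applyMvpPenalty(matrix(150), 100, 0.2), matrix(150))
  expect_equal(applyMvpPenalty(matrix(0), 100, 0.2), matrix(0))
  set.seed(2)
  out <- replicate(2000, applyMvpPenalty(matrix(50), 100, 0.2, round = FALSE)[1, 1])
  expect_lt(abs(mean(out) - 40), 0.2) # 20% mean mortality below threshold
})

test_that("beta moment matching reproduces the closed-form shape parameters", {
  sh <- betaShapes(0.5, 0.05)
  expect_equal(unname(sh), c(49.5, 49.5))
  # matched draws have the requested moments
  set.seed(3)
  x <- rbeta(2e4, sh[1], sh[2])
  expect_lt(abs(mean(x) - 0.5), 0.002)
  expect_lt(abs(sd(x) - 0.05), 0.003)
  expect_error(betaShapes(0.5, 0.6), "sd")
})

test_that("catastrophes remove the beta-distributed share of struck cells only", {
  N <- matrix(1000, 10, 10)
  expect_equal(applyCatastrophes(N, integer(0), 0.5), N)
  set.seed(4)
  hit <- applyCatastrophes(matrix(1000, 1, 1e4), seq_len(1e4), 0.5,
                           round = FALSE)
  expect_lt(abs(mean(hit) - 500), 15)
  # severity sampled per cell: spread matches SD = mCat / 10 of N
  expect_lt(abs(sd(as.vector(hit)) - 50), 5)
})

test_that("the Thomas sampler calibrates to the target marginal strike rate", {
  set.seed(6)
  occ <- matrix(runif(40 * 40) < 0.5, 40, 40)
  sc <- calibrateCatastropheIntensity(occ, thomasParams(), pCat = 0.14,
                                      nGen = 150)
  hits <- replicate(400, length(sampleCatastropheCells(occ, thomasParams(), sc)))
  expect_lt(abs(mean(hits) / sum(occ) - 0.14), 0.03)
  # degenerate targets
  expect_equal(calibrateCatastropheIntensity(occ, thomasParams(), 0), 0)
  expect_length(sampleCatastropheCells(occ, thomasParams(), 0), 0)
  expect_length(sampleCatastropheCells(matrix(FALSE, 3, 3), thomasParams(), 5), 0)
})

test_that("struck cells are spatially clustered relative to independent thinning", {
  set.seed(7)
  occ <- matrix(runif(50 * 50) < 0.5, 50, 50)
  sc <- calibrateCatastropheIntensity(occ, thomasParams(), 0.14, nGen = 100)
  # pair count within radius 3 as a Ripley-type clustering statistic
  pairStat <- function(cells) {
    if (length(cells) < 2) return(0)
    r <- (cells - 1) %% 50 + 1; cl <- (cells - 1) %/% 50 + 1
    D2 <- outer(r, r, "-")^2 + outer(cl, cl, "-")^2
    (sum(D2 <= 9) - length(cells)) / length(cells)
  }
  occIdx <- which(occ)
  thomasStat <- thinStat <- numeric(60)
  for (i in 1:60) {
    cells <- sampleCatastropheCells(occ, thomasParams(), sc)
    thomasStat[i] <- pairStat(cells)
    # CSR oracle: binomial thinning of occupied cells at the same count
    thinStat[i] <- pairStat(sample(occIdx, length(cells)))
  }
  expect_gt(mean(thomasStat), mean(thinStat) + 3 * sd(thinStat) / sqrt(60))
})
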