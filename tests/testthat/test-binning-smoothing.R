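test_that("binning counts frames and accumulates signal", {
  frames <- data.frame(t = c(1, 2, 3), trialId = 1L,
                       z = c(10.1, 10.6, 11.4), theta = c(0.5, 1.1, 0.2))
  s <- manualSession(frames)
  g <- defaultGrid()
  maps <- binTrajectory(s, c(1, 2, 3), g)
  occ <- occupancy(maps); sig <- signalMap(maps)
  iz <- findInterval(10.1, g@zEdges)
  it <- findInterval(0.5, g@thetaEdges)
  expect_equal(occ[iz, it], 3)
  expect_equal(sig[iz, it], 6)
  expect_equal(sum(occ), 3)
  expect_equal(sum(sig), 6)
})

test_that("an empty mask yields identically zero maps", {
  s <- smallSession(10, 7)
  maps <- binTrajectory(s, rnorm(ncol(s)), defaultGrid(),
                        frameMask = rep(FALSE, ncol(s)))
  expect_true(all(occupancy(maps) == 0))
  expect_true(all(signalMap(maps) == 0))
})

test_that("binning conserves total occupancy and signal", {
  s <- smallSession(10, 7)
  tr <- rnorm(ncol(s))
  maps <- binTrajectory(s, tr, defaultGrid())
  expect_equal(sum(occupancy(maps)), ncol(s))
  expect_equal(sum(signalMap(maps)), sum(tr), tolerance = 1e-12)
  ## signal is zero wherever occupancy is zero (class validity)
  expect_true(all(signalMap(maps)[occupancy(maps) == 0] == 0))
})

test_that("bin edges follow the half-open convention with a closed end", {
  frames <- data.frame(t = 1:4, trialId = 1L,
                       z = c(2, 5, 110, 109), theta = c(0, 0, 0, 0))
  s <- manualSession(frames)
  g <- defaultGrid()
  maps <- binTrajectory(s, rep(1, 4), g)
  it <- findInterval(0, g@thetaEdges)
  expect_equal(occupancy(maps)[2, it], 1)   # z = 2 goes to [2, 4)
  expect_equal(occupancy(maps)[55, it], 2)  # z = 110 closes the last bin
})

test_that("frames outside the grid raise an error rather than dropping", {
  s <- smallSession(10, 7)
  shortGrid <- gridSpec(seq(0, 100, 2), seq(-90, 90, 3))
  expect_error(binTrajectory(s, rnorm(ncol(s)), shortGrid), "out-of-range")
})

test_that("smoothing conserves mass and preserves constants", {
  for (seed in 1:8) {
    inst <- randomMapsInstance(seed)
    m <- occupancy(inst$maps)
    sm <- smoothMap(m, inst$grid, inst$bw)
    expect_lt(abs(sum(sm) - sum(m)), 1e-9 * max(sum(m), 1))
    const <- matrix(2.7, nrow(m), ncol(m))
    expect_equal(smoothMap(const, inst$grid, inst$bw), const,
                 tolerance = 1e-12)
  }
  ## delta map becomes a unit-mass bump
  g <- defaultGrid()
  d <- gridDim(g)
  delta <- matrix(0, d[1], d[2]); delta[20, 30] <- 1
  sm <- smoothMap(delta, g, bandwidths(4, 6))
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_gt(max(sm), sm[1, 1])
})

test_that("a smoothed delta has the kernel variance", {
  g <- gridSpec(seq(0, 110, 1), seq(-90, 90, 1))
  d <- gridDim(g)
  delta <- matrix(0, d[1], d[2]); delta[55, 90] <- 1
  sm <- smoothMap(delta, g, bandwidths(3, 5))
  zc <- zCenters(g)
  mz <- rowSums(sm)
  varZ <- sum(mz * zc^2) - sum(mz * zc)^2
  expect_lt(abs(varZ - 9) / 9, 0.03)
  tc <- thetaCenters(g)
  mt <- colSums(sm)
  varT <- sum(mt * tc^2) - sum(mt * tc)^2
  expect_lt(abs(varT - 25) / 25, 0.03)
})

test_that("field lookup is exact at bin centers", {
  g <- gridSpec(seq(0, 10, 2), seq(-9, 9, 3))
  set.seed(1)
  V <- matrix(rnorm(gridDim(g)[1] * gridDim(g)[2]), gridDim(g)[1])
  zq <- zCenters(g)[c(2, 4)]
  tq <- thetaCenters(g)[c(1, 5)]
  expect_equal(fieldLookup(V, zq, tq, grid = g),
               V[cbind(c(2, 4), c(1, 5))], tolerance = 1e-12)
  expect_equal(fieldLookup(V, zq, tq, method = "nearest", grid = g),
               V[cbind(c(2, 4), c(1, 5))], tolerance = 1e-12)
  ## clamped outside the centers
  expect_equal(fieldLookup(V, -5, 0, grid = g),
               fieldLookup(V, zCenters(g)[1], 0, grid = g))
})

test_that("invalid bandwidths are rejected", {
  expect_error(bandwidths(-1, 3))
  expect_error(bandwidths(2, 0))
})
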