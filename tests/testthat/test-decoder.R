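test_that("sigma estimates use population variance with a floor", {
  expect_equal(estimateSigmaI(c(0, 2))$sigma, 1)
  const <- estimateSigmaI(rep(5, 10))
  expect_true(const$floored)
  expect_gt(const$sigma, 0)
  set.seed(1)
  x <- rnorm(1e4)
  expect_lt(abs(estimateSigmaI(x)$sigma - 1), 0.05)
  expect_error(estimateSigmaI(3), "frames")
})

test_that("the log posterior matches the closed form", {
  g <- gridSpec(c(0, 1, 2), c(0, 1, 2))
  uni <- matrix(0.25, 2, 2)
  ## one neuron, mu 0 in column 1 and 1 in column 2, r = 1, sigma = 1
  mu <- matrix(c(0, 0, 1, 1), 2, 2)
  lp <- logPosterior(1, list(mu), 1, uni, grid = g)
  expect_equal(lp$logPost[1, 2] - lp$logPost[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(unname(lp$mapBin), c(1, 2))  # first max in z-outer order
  ## zero neurons: posterior is the log prior, MAP is the prior mode
  pr <- matrix(c(0.1, 0.2, 0.4, 0.3), 2, 2)
  lp0 <- logPosterior(numeric(0), list(), numeric(0), pr, grid = g)
  expect_equal(lp0$logPost, log(pr))
  expect_equal(unname(lp0$mapBin), c(1, 2))
  ## doubling every sigma scales the likelihood by 1/4, MAP unchanged
  set.seed(2)
  mus <- replicate(3, matrix(rnorm(4), 2, 2), simplify = FALSE)
  r <- rnorm(3); sg <- runif(3, 0.5, 2)
  a <- logPosterior(r, mus, sg, uni, grid = g)
  b <- logPosterior(r, mus, 2 * sg, uni, grid = g)
  expect_equal(b$logPost - log(uni), (a$logPost - log(uni)) / 4,
               tolerance = 1e-12)
  expect_equal(a$mapBin, b$mapBin)
})

test_that("the log posterior matches a brute-force triple loop", {
  for (seed in 1:5) {
    set.seed(seed)
    nz <- sample(2:6, 1); nt <- sample(2:6, 1); nn <- sample(1:6, 1)
    g <- gridSpec(seq(0, nz), seq(0, nt))
    mus <- replicate(nn, matrix(rnorm(nz * nt), nz, nt), simplify = FALSE)
    r <- rnorm(nn); sg <- runif(nn, 0.3, 2)
    pr <- matrix(runif(nz * nt), nz, nt); pr <- pr / sum(pr)
    lp <- logPosterior(r, mus, sg, pr, grid = g)
    ref <- bruteLogPosterior(r, mus, sg, pr)
    expect_lt(max(abs(lp$logPost - ref)), 1e-10 * max(abs(ref)))
  }
})

test_that("a uniform prior makes the posterior translation invariant", {
  set.seed(3)
  g <- gridSpec(seq(0, 5), seq(0, 4))
  uni <- matrix(1 / 20, 5, 4)
  mus <- replicate(4, matrix(rnorm(20), 5, 4), simplify = FALSE)
  r <- rnorm(4); sg <- runif(4, 0.5, 2)
  a <- logPosterior(r, mus, sg, uni, grid = g)
  shifted <- lapply(mus, function(m) m + 3.7)
  b <- logPosterior(r + 3.7, shifted, sg, uni, grid = g)
  expect_equal(a$logPost, b$logPost, tolerance = 1e-9)
})

test_that("a zero-noise population identifies the true bin", {
  g <- defaultGrid()
  pop <- generatePopulation(100, seed = 41, noiseScale = 0)
  mus <- truthFieldMatrix(pop, g)
  d <- gridDim(g)
  uni <- matrix(1 / prod(d), d[1], d[2])
  set.seed(42)
  hits <- 0; n <- 200
  for (k in seq_len(n)) {
    iz <- sample(d[1], 1); it <- sample(d[2], 1)
    r <- vapply(seq_len(nrow(pop)), function(i)
      truthFieldValue(pop[i, ], zCenters(g)[iz], thetaCenters(g)[it]),
      numeric(1))
    lp <- logPosterior(r, mus, rep(0.05, nrow(pop)), uni, grid = g)
    if (lp$mapBin[1] == iz && lp$mapBin[2] == it) hits <- hits + 1
  }
  expect_gte(hits / n, 0.99)
})

test_that("a flat likelihood decodes the prior mode", {
  s <- fixture("noisySess", function() {
    pop <- manualPopulation(c(40, 70), c(-10, 10), 15, 20, amplitude = 1,
                            baseline = 0, sigma = 1)
    generateResponses(smallSession(12, 51), pop, seed = 52)
  })
  g <- defaultGrid()
  ## enormous sigma_i flattens the likelihood entirely
  dec <- decodeSession(s, g, fieldBw = bandwidths(4, 6),
                       sigmas = rep(1e9, 2))
  traj <- trajectory(s)
  for (id in trials(s)$trialId[1:4]) {
    pr <- occupancyPrior(s, g, frameMask = traj$trialId != id)
    k <- which.max(as.vector(t(pr)))
    nt <- gridDim(g)[2]
    zMode <- zCenters(g)[(k - 1) %/% nt + 1]
    tMode <- thetaCenters(g)[(k - 1) %% nt + 1]
    sel <- dec$decoded$trialId == id
    expect_true(all(dec$decoded$zMap[sel] == zMode))
    expect_true(all(dec$decoded$thetaMap[sel] == tMode))
  }
})

test_that("leave-one-trial-out bookkeeping measurably matters", {
  p <- generatePopulation(15, seed = 20, noiseScale = 1)
  s <- generateResponses(simulateSession(simulationConfig(nTrials = 10,
                                                          seed = 21)),
                         p, seed = 22)
  honest <- decodeSession(s, fieldBw = bandwidths(2, 3))
  cheat <- decodeSession(s, fieldBw = bandwidths(2, 3),
                         includeOwnTrial = TRUE)
  errH <- median(abs(honest$decoded$zMap - honest$decoded$zTrue))
  errC <- median(abs(cheat$decoded$zMap - cheat$decoded$zTrue))
  expect_lt(errC, errH)
})

test_that("neurometric analysis equals behavior for a perfect decoder", {
  s <- smallSession(60, 61)
  traj <- trajectory(s)
  fake <- list(decoded = data.frame(
    frame = seq_len(nrow(traj)), trialId = traj$trialId,
    zTrue = traj$z, thetaTrue = traj$theta,
    zMap = traj$z, thetaMap = traj$theta,
    logPostMax = 0))
  cps <- c(20, 40, 60, 80, 100)
  nm <- neurometricChoice(fake, s, cps, seed = 5)
  hp <- headingChoicePredictability(s, cps, seed = 5)
  expect_equal(nm$curve$predictability, hp$curve$predictability,
               tolerance = 1e-12)
  expect_equal(nm$curve$se, hp$curve$se, tolerance = 1e-12)
})

test_that("decoding requires neurons and at least two trials", {
  s <- smallSession(10, 7)
  expect_error(decodeSession(s), "neuron")
})
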