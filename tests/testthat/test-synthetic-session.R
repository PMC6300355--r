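test_that("a fixed seed reproduces the session and responses exactly", {
  cfg <- simulationConfig(nTrials = 15, seed = 42)
  s1 <- simulateSession(cfg)
  s2 <- simulateSession(cfg)
  expect_identical(trials(s1), trials(s2))
  expect_identical(trajectory(s1), trajectory(s2))
  pop <- generatePopulation(3, seed = 5)
  expect_identical(pop, generatePopulation(3, seed = 5))
  r1 <- responses(generateResponses(s1, pop, seed = 6))
  r2 <- responses(generateResponses(s2, pop, seed = 6))
  expect_identical(r1, r2)
  t1 <- simulateTrial(0.25, cfg, seed = 9)
  t2 <- simulateTrial(0.25, cfg, seed = 9)
  expect_identical(t1, t2)
})

test_that("choice fractions follow the psychometric model", {
  ## symmetric at zero contrast
  s0 <- simulateSession(simulationConfig(nTrials = 400, contrastSet = 0,
                                         seed = 1))
  fR <- mean(trials(s0)$choice == "R")
  expect_lt(abs(fR - 0.5), 3 * sqrt(0.25 / 400))
  ## saturates at 1 - lapse for full contrast
  s1 <- simulateSession(simulationConfig(nTrials = 400, contrastSet = 1,
                                         lapseRate = 0.05, seed = 2))
  fR <- mean(trials(s1)$choice == "R")
  expect_lt(abs(fR - 0.95), 3 * sqrt(0.95 * 0.05 / 400))
})

test_that("contrasts are drawn uniformly from the contrast set", {
  s <- simulateSession(simulationConfig(
    nTrials = 4000, contrastSet = c(-0.5, -0.125, 0.125, 0.5), seed = 3))
  counts <- table(trials(s)$contrast)
  expect_equal(length(counts), 4)
  sd <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) < 3 * sd))
})

test_that("baiting repeats error trials with the same stimulus", {
  s <- simulateSession(simulationConfig(nTrials = 60, baitingEnabled = TRUE,
                                        lapseRate = 0.1, seed = 4))
  tr <- trials(s)
  expect_equal(sum(!tr$isRepeat), 60)
  reps <- which(tr$isRepeat)
  expect_gt(length(reps), 0)  # with lapses some errors must occur
  for (k in reps) {
    expect_identical(tr$contrast[k], tr$contrast[k - 1])
    expect_false(tr$correct[k - 1])
  }
  sOff <- simulateSession(simulationConfig(nTrials = 40, seed = 4))
  expect_false(any(trials(sOff)$isRepeat))
})

test_that("a one-trial session has exactly one non-repeat trial", {
  s <- simulateSession(simulationConfig(nTrials = 1, seed = 5))
  expect_equal(nTrials(s), 1)
  expect_false(trials(s)$isRepeat)
  expect_gte(sum(trajectory(s)$trialId == trials(s)$trialId), 2)
})

test_that("trajectories respect maze geometry across random configs", {
  geom <- mazeGeometry()
  for (seed in 1:5) {
    set.seed(seed + 100)
    cfg <- simulationConfig(nTrials = 10,
                            headingNoiseSd = runif(1, 5, 60),
                            headingDriftGain = runif(1, 0.5, 4),
                            forwardSpeed = runif(1, 10, 35),
                            seed = seed)
    traj <- trajectory(simulateSession(cfg, geom))
    expect_true(all(traj$z >= 0 & traj$z <= corridorLength(geom)))
    expect_true(all(traj$theta >= headingBounds(geom)[1] &
                      traj$theta <= headingBounds(geom)[2]))
    expect_true(all(tapply(traj$t, traj$trialId, function(x) all(diff(x) > 0))))
    expect_true(all(table(traj$trialId) >= 2))
  }
})

test_that("choice-conditioned heading separation grows with contrast", {
  s <- smallSession(nTrials = 800, seed = 5)
  tr <- trials(s); traj <- trajectory(s)
  th80 <- vapply(tr$trialId, function(id) {
    i <- which(traj$trialId == id)
    traj$theta[i[traj$z[i] >= 80][1]]
  }, numeric(1))
  sep <- vapply(c(0, 0.125, 0.25, 0.5), function(lev) {
    sel <- abs(tr$contrast) == lev
    mean(th80[sel & tr$choice == "R"]) - mean(th80[sel & tr$choice == "L"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("responses equal the tuning surface when noise is zero", {
  s <- smallSession(nTrials = 10, seed = 7)
  pop <- manualPopulation(60, 20, 15, 18, amplitude = 1.5, baseline = 0.1)
  r <- responses(generateResponses(s, pop, seed = 1))[1, ]
  traj <- trajectory(s)
  expect_equal(r, truthFieldValue(pop[1, ], traj$z, traj$theta),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## zero amplitude: constant baseline
  flat <- manualPopulation(60, 0, 15, 18, amplitude = 0, baseline = 0.7)
  rf <- responses(generateResponses(s, flat, seed = 2))[1, ]
  expect_true(all(rf == 0.7))
})

test_that("response noise has the configured standard deviation", {
  s <- smallSession(nTrials = 250, seed = 8)
  expect_gte(ncol(s), 1e4)
  pop <- manualPopulation(60, 0, 15, 18, amplitude = 0, baseline = 0, sigma = 1)
  r <- responses(generateResponses(s, pop, seed = 3))[1, ]
  expect_lt(abs(sd(r) - 1), 0.05)
})

test_that("deltaF/F uses the 20th percentile baseline", {
  expect_true(all(computeDff(rep(3.5, 50)) == 0))
  x <- 1:100
  f0 <- 20.8  # linear-interpolation 20th percentile of 1..100
  dff <- computeDff(x)
  expect_equal(dff[100], (100 - f0) / f0, tolerance = 1e-12)
  expect_equal(dff[1], (1 - f0) / f0, tolerance = 1e-12)
  ## distinct values: about 20% of samples fall below the baseline
  for (seed in 1:3) {
    set.seed(seed)
    v <- runif(80, 1, 10)
    nNeg <- sum(computeDff(v) < 0)
    expect_lte(abs(nNeg - floor(0.2 * 80)), 1)
  }
  expect_error(computeDff(c(-5, -4, 1, 2, 3)), "baseline")
})

test_that("invalid simulation parameters are rejected", {
  cfg <- simulationConfig(nTrials = 5, seed = 1)
  expect_error(simulateTrial(1.5, cfg), "contrast")
  expect_error(simulationConfig(contrastSet = numeric(0)))
  expect_error(simulationConfig(lapseRate = 0.6), "lapse")
  expect_error(simulationConfig(nTrials = 0), "nTrials")
  expect_error(generateResponses(smallSession(10, 7),
                                 manualPopulation(numeric(0), numeric(0), 1, 1)),
               "empty")
})

test_that("population fields tile the reachable maze region", {
  geom <- mazeGeometry()
  pop <- generatePopulation(500, geom, seed = 11)
  expect_true(all(pop$centerZ > 0 & pop$centerZ < corridorLength(geom)))
  expect_true(all(abs(pop$centerTheta) <= headingBounds(geom)[2]))
  expect_true(all(pop$widthZ > 0 & pop$widthTheta > 0 & pop$amplitude >= 0))
  one <- generatePopulation(1, geom, seed = 12)
  expect_equal(nrow(one), 1)
})
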