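test_that("the regularized ratio matches direct arithmetic on a 2x2 grid", {
  g <- gridSpec(c(0, 1, 2), c(0, 1, 2))
  maps <- new("BinnedMaps",
              occupancy = matrix(c(2, 1, 0, 1), 2, 2),
              signal = matrix(c(4, 1, 0, 3), 2, 2), grid = g)
  f <- estimateField(maps, bandwidths(1e-12, 1e-12), lambda = 1, fMean = 2)
  expect_equal(fieldValues(f), matrix(c(2, 1.5, 2, 2.5), 2, 2),
               tolerance = 1e-12)
})

test_that("the estimator matches a brute-force evaluation", {
  for (seed in 1:5) {
    inst <- randomMapsInstance(seed)
    f <- estimateField(inst$maps, inst$bw, inst$lambda, inst$fMean)
    ref <- bruteEstimateField(occupancy(inst$maps), signalMap(inst$maps),
                              diff(inst$grid@zEdges)[1],
                              diff(inst$grid@thetaEdges)[1],
                              sigmaZ(inst$bw), sigmaTheta(inst$bw),
                              inst$lambda, inst$fMean)
    expect_lt(max(abs(fieldValues(f) - ref)) / max(abs(ref)), 1e-10)
  }
})

test_that("extreme regularization pulls the field to the mean response", {
  inst <- randomMapsInstance(3)
  fMean <- 1.7
  lam <- 1e9 * max(occupancy(inst$maps))
  f <- estimateField(inst$maps, inst$bw, lam, fMean)
  expect_lt(max(abs(fieldValues(f) - fMean)), 1e-6 * fMean)
})

test_that("a constant trace yields a constant field at any occupancy", {
  s <- smallSession(10, 7)
  maps <- binTrajectory(s, rep(3.2, ncol(s)), defaultGrid())
  f <- estimateField(maps, bandwidths(8, 12), lambda = 1, fMean = 3.2)
  expect_equal(max(abs(fieldValues(f) - 3.2)), 0, tolerance = 1e-12)
})

test_that("the cross-validation error is the normalized squared error", {
  frames <- data.frame(t = 1:4, trialId = c(1L, 1L, 2L, 2L),
                       z = c(10, 30, 50, 70), theta = c(-10, 0, 10, 20))
  s <- manualSession(frames)
  g <- defaultGrid()
  ## a constant field predicting 2 for a test trace [1, 3] with train mean 2
  maps <- binTrajectory(s, rep(2, 4), g)
  f <- estimateField(maps, bandwidths(4, 6), 1, 2)
  expect_equal(cvErrorTrace(s, c(1, 3, 0, 0), 1:2, f, fMeanTrain = 2), 1)
  ## perfect prediction: trace equals the field along the trajectory
  traj <- trajectory(s)
  tr <- fieldLookup(f, traj$z, traj$theta)
  expect_equal(cvErrorTrace(s, tr + 0, 1:4, f, fMeanTrain = 0), 0)
  ## field identical to the training mean gives exactly 1
  expect_equal(cvErrorTrace(s, c(1, 3, 1, 3), 1:4, f, fMeanTrain = 2), 1)
  ## brute-force agreement on random instances
  for (seed in 1:5) {
    set.seed(seed)
    trace <- rnorm(4); fm <- rnorm(1)
    pred <- fieldLookup(f, traj$z, traj$theta)
    expect_equal(cvErrorTrace(s, trace, 1:4, f, fm),
                 bruteCvError(pred, trace, fm), tolerance = 1e-12)
  }
  expect_error(cvErrorTrace(s, rep(5, 4), 1:4, f, 5), "degenerate")
})

test_that("bandwidth selection is deterministic and minimizes the error", {
  s <- fixture("fieldSess", function() {
    pop <- manualPopulation(60, 10, 14, 16, amplitude = 1.5, sigma = 0.4)
    generateResponses(smallSession(50, 21), pop, seed = 2)
  })
  g <- defaultGrid()
  cfg <- estimatorConfig(nFolds = 5, foldSeed = 3)
  fit1 <- selectBandwidths(s, responses(s)[1, ], g, cfg)
  fit2 <- selectBandwidths(s, responses(s)[1, ], g, cfg)
  expect_identical(fit1$bandwidths, fit2$bandwidths)
  expect_identical(fieldValues(fit1$field), fieldValues(fit2$field))
  ## the selected candidate attains the minimum mean error
  expect_equal(cvError(fit1$field), min(fit1$cvTable$epsilon))
  expect_true(all(cvError(fit1$field) <= fit1$cvTable$epsilon))
  ## a single candidate is always returned
  one <- estimatorConfig(bandwidthCandidates = data.frame(sigmaZ = 6,
                                                          sigmaTheta = 9),
                         nFolds = 5)
  expect_equal(sigmaZ(selectBandwidths(s, responses(s)[1, ], g, one)$bandwidths), 6)
})

test_that("broader tuning selects a broader position bandwidth", {
  wins <- 0
  for (rep in 1:10) {
    sess <- simulateSession(simulationConfig(nTrials = 50, seed = 300 + rep))
    pop <- manualPopulation(c(55, 55), c(0, 0), widthZ = c(30, 6),
                            widthTheta = 20, amplitude = 1,
                            sigma = 0.3)
    s <- generateResponses(sess, pop, seed = 400 + rep)
    cfg <- estimatorConfig(nFolds = 5, foldSeed = rep)
    szBroad <- sigmaZ(selectBandwidths(s, responses(s)[1, ], defaultGrid(), cfg)$bandwidths)
    szNarrow <- sigmaZ(selectBandwidths(s, responses(s)[2, ], defaultGrid(), cfg)$bandwidths)
    if (szBroad > szNarrow) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("selection requires at least as many trials as folds", {
  s <- smallSession(5, 7)
  expect_error(selectBandwidths(s, rnorm(ncol(s)), defaultGrid(),
                                estimatorConfig(nFolds = 10)),
               "trials")
})
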