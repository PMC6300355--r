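## session with controlled theta samples in chosen z-bins
aurocSession <- function(thetaL, thetaR, zLo = 0, zStep = 10) {
  nL <- length(thetaL); nR <- length(thetaR)
  frames <- rbind(
    data.frame(t = seq_len(nL), trialId = 1L, z = zLo + zStep / 2,
               theta = thetaL),
    data.frame(t = nL + seq_len(nR), trialId = 2L, z = zLo + zStep / 2,
               theta = thetaR))
  manualSession(frames, choices = c("L", "R"))
}

test_that("auROC matches exhaustive pair counting", {
  for (seed in 1:3) {
    set.seed(seed)
    thetaL <- round(runif(sample(3:30, 1), -40, 40))
    thetaR <- round(runif(sample(3:30, 1), -40, 40))
    s <- aurocSession(thetaL, thetaR)
    mask <- aurocExclusion(s, c(0, 10), threshold = 0.95)
    a <- bruteAuroc(thetaL, thetaR)
    expect_equal(mask$auroc, max(a, 1 - a), tolerance = 1e-12)
  }
})

test_that("auROC boundary cases behave as defined", {
  ## perfect separation: excluded
  m <- aurocExclusion(aurocSession(c(-10, -5), c(5, 10)), c(0, 10))
  expect_equal(m$auroc, 1)
  expect_true(m$excluded)
  ## identical distributions: retained at 0.5
  m <- aurocExclusion(aurocSession(c(-3, 0, 3), c(-3, 0, 3)), c(0, 10))
  expect_equal(m$auroc, 0.5)
  expect_false(m$excluded)
  ## 3 of 4 cross-pairs ordered: 0.75, retained
  m <- aurocExclusion(aurocSession(c(-1, 2), c(1, 3)), c(0, 10))
  expect_equal(m$auroc, 0.75)
  expect_false(m$excluded)
  ## bins visited by one class only are excluded by convention
  s <- aurocSession(c(-5, -2), c(2, 5))
  m <- aurocExclusion(s, c(0, 10, 20))
  expect_true(m$excluded[2])
  expect_true(is.na(m$auroc[2]))
})

test_that("lowering the threshold never retains more bins", {
  s <- smallSession(80, 13)
  zE <- defaultGrid()@zEdges
  hi <- aurocExclusion(s, zE, threshold = 0.95)
  lo <- aurocExclusion(s, zE, threshold = 0.8)
  expect_true(all(lo$excluded[hi$excluded]))
  expect_lte(sum(!lo$excluded), sum(!hi$excluded))
})

test_that("trial-averaged correlation scores match hand computation", {
  frames <- data.frame(t = 1:8, trialId = rep(1:4, each = 2),
                       z = rep(c(20, 40), 4), theta = 0)
  s <- manualSession(frames)
  actual <- rep(c(1, 2, 3, 4), each = 2)
  predicted <- rep(c(1, 1, 3, 3), each = 2)
  expect_equal(fitQuality(actual, predicted, s), 4 / sqrt(20),
               tolerance = 1e-12)
  expect_equal(fitQuality(actual, actual, s), 1)
  expect_equal(fitQuality(actual, -actual, s), -1)
  ## zero variance in a trial-mean vector is reported as missing
  expect_true(is.na(fitQuality(actual, rep(2, 8), s)))
})

test_that("prediction honors the cross-validation contract", {
  s <- fixture("fieldSess", function() {
    pop <- manualPopulation(60, 10, 14, 16, amplitude = 1.5, sigma = 0.4)
    generateResponses(smallSession(50, 21), pop, seed = 2)
  })
  fit <- selectBandwidths(s, responses(s)[1, ], defaultGrid(),
                          estimatorConfig(nFolds = 5))
  ## the refit field was trained on every trial
  expect_error(predictTrace(fit$field, s, trials(s)$trialId[1]),
               "contract")
  ## a field with no recorded training trials predicts anywhere
  f <- fit$field; f@trainedTrials <- integer(0)
  p <- predictTrace(f, s)
  expect_equal(length(p), ncol(s))
  ## a constant field predicts a constant
  fc <- f; fc@values[] <- 1.23
  expect_equal(as.numeric(predictTrace(fc, s)), rep(1.23, ncol(s)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("decision models are split by choice and flat in theta for f(z,d)", {
  s <- fixture("zOnlySess", function() {
    pop <- manualPopulation(55, 0, 16, 1e6, amplitude = 1.2, sigma = 0.12)
    generateResponses(smallSession(100, 23), pop, seed = 3)
  })
  cfg <- estimatorConfig(nFolds = 5)
  zd <- fitDecisionModel(s, responses(s)[1, ], defaultGrid(), cfg,
                         includeTheta = FALSE)
  ## each sub-model's prediction is flat across theta
  for (sub in list(zd@left, zd@right)) {
    v <- fieldValues(sub)
    expect_lt(max(abs(v[, 1] - v[, 2])), 1e-9)
  }
  ## a z-only neuron gives closely matching left/right profiles
  expect_gt(cor(fieldValues(zd@left)[, 1], fieldValues(zd@right)[, 1]), 0.95)
  ## a single-choice session cannot fit a decision model
  oneChoice <- manualSession(
    data.frame(t = 1:8, trialId = rep(1:4, each = 2),
               z = rep(c(20, 40), 4), theta = 0),
    choices = rep("L", 4))
  expect_error(fitDecisionModel(oneChoice, rnorm(8), defaultGrid(),
                                estimatorConfig(nFolds = 2)),
               "choice class")
})

test_that("noiseless nested models never favor the decision variant", {
  s <- fixture("noiselessSess", function() {
    sess <- smallSession(60, 31)
    pop <- generatePopulation(4, seed = 32, noiseScale = 0)
    generateResponses(sess, pop, seed = 33)
  })
  rep <- compareModels(s, config = estimatorConfig(nFolds = 5))
  expect_true(all(rep$perNeuron$rZT >= rep$perNeuron$rZD))
})

test_that("choice sequences order neurons by field position", {
  s <- fixture("seqSess", function() {
    sess <- smallSession(80, 9)
    pop <- manualPopulation(centerZ = seq(15, 95, length.out = 8),
                            centerTheta = 0, widthZ = 10, widthTheta = 1e6,
                            amplitude = 1, sigma = 0.05)
    generateResponses(sess, pop, seed = 10)
  })
  sq <- buildChoiceSequences(s, responses(s))
  pop <- S4Vectors::metadata(s)$population
  for (cl in c("L", "R")) {
    sel <- sq$ordering[sq$ordering$class == cl, ]
    if (nrow(sel) >= 3)
      expect_equal(cor(sel$peakBin, pop$centerZ[sel$neuron],
                       method = "spearman"), 1)
  }
  ## rows are peak-normalized
  expect_true(all(abs(apply(rbind(sq$left, sq$right), 1, max) - 1) < 1e-9))
  ## one neuron: a single 1-row matrix with unit peak
  one <- buildChoiceSequences(s, responses(s)[1, , drop = FALSE])
  expect_equal(nrow(one$left) + nrow(one$right), 1)
  ## reusing an ordering preserves the neuron arrangement
  sq2 <- buildChoiceSequences(s, responses(s), ordering = sq$ordering)
  expect_identical(sq2$ordering$neuron, sq$ordering$neuron)
})
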