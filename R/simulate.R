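## Synthetic-session generator: trajectories, choices, psychometric behavior
## and neural responses with the statistical structure the downstream
## analyses assume.

#' Simulation configuration
#'
#' Parameters of the synthetic behavioral model. The per-trial choice is
#' drawn first from a lapse-equipped cumulative-Gaussian psychometric
#' function of signed stimulus contrast; the heading trajectory then drifts
#' (Ornstein-Uhlenbeck-style) toward a target angle on the chosen side while
#' the animal advances along the corridor at near-constant speed. Drift rate
#' grows with |contrast|, so trajectories toward the two choices diverge
#' sooner on easier trials.
#'
#' @param nTrials number of non-repeat trials.
#' @param contrastSet signed contrasts in [-1, 1]; negative = stimulus on the
#'   left wall.
#' @param psychometricSlope slope of the generating sigmoid (1/contrast).
#' @param psychometricBias horizontal bias of the sigmoid (contrast units).
#' @param lapseRate lapse probability in [0, 0.5).
#' @param headingDriftGain Ornstein-Uhlenbeck relaxation rate per unit
#'   decision drive (1/s); the effective rate is
#'   \code{headingDriftGain * (0.25 + |contrast|)}.
#' @param headingNoiseSd heading diffusion noise (deg s^-1 Hz^-1/2).
#' @param thetaTarget magnitude of the target heading angle (deg) the
#'   trajectory drifts toward on the chosen side.
#' @param forwardSpeed mean forward speed (cm/s).
#' @param speedNoiseSd SD of per-frame forward-speed noise (cm/s).
#' @param baitingEnabled if TRUE, an error trial is followed by repeats of
#'   the same stimulus (flagged \code{isRepeat}) until answered correctly.
#' @param frameRate sampling rate (Hz).
#' @param interTrialInterval gap in the global time base between trials (s).
#' @param seed RNG seed; fixes the session exactly.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(nTrials = 20, seed = 1)
#' @export
simulationConfig <- function(nTrials = 200,
                             contrastSet = c(-0.5, -0.25, -0.125, 0,
                                             0.125, 0.25, 0.5),
                             psychometricSlope = 8,
                             psychometricBias = 0,
                             lapseRate = 0.05,
                             headingDriftGain = 1.6,
                             headingNoiseSd = 25,
                             thetaTarget = 65,
                             forwardSpeed = 20,
                             speedNoiseSd = 2,
                             baitingEnabled = FALSE,
                             frameRate = 7.5,
                             interTrialInterval = 2,
                             seed = 1) {
  stopIfNot(nTrials >= 1, "nTrials must be >= 1")
  stopIfNot(length(contrastSet) >= 1, "contrastSet must not be empty")
  stopIfNot(all(abs(contrastSet) <= 1), "contrasts must lie in [-1, 1]")
  stopIfNot(lapseRate >= 0 && lapseRate < 0.5, "lapseRate must be in [0, 0.5)")
  stopIfNot(forwardSpeed > 0, "forwardSpeed must be positive")
  stopIfNot(frameRate > 0, "frameRate must be positive")
  structure(list(nTrials = as.integer(nTrials), contrastSet = contrastSet,
                 psychometricSlope = psychometricSlope,
                 psychometricBias = psychometricBias, lapseRate = lapseRate,
                 headingDriftGain = headingDriftGain,
                 headingNoiseSd = headingNoiseSd, thetaTarget = thetaTarget,
                 forwardSpeed = forwardSpeed, speedNoiseSd = speedNoiseSd,
                 baitingEnabled = isTRUE(baitingEnabled),
                 frameRate = frameRate,
                 interTrialInterval = interTrialInterval,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Psychometric choice probability
#'
#' P(rightward | contrast) under the lapse-equipped cumulative-Gaussian model
#' \code{lapse + (1 - 2 lapse) * Phi(slope * (contrast - bias))}. This is
#' both the generating model of the simulator and the form fitted by
#' \code{\link{psychometric}}.
#'
#' @param contrast signed contrast(s).
#' @param slope,bias,lapse sigmoid parameters.
#' @return probability of a rightward choice.
#' @examples
#' psychometricProb(c(-0.5, 0, 0.5), slope = 8, lapse = 0.05)
#' @export
psychometricProb <- function(contrast, slope, bias = 0, lapse = 0) {
  lapse + (1 - 2 * lapse) * stats::pnorm(slope * (contrast - bias))
}

## Core trajectory generator; assumes the RNG state is already set by the
## caller. Returns list(trial = one-row data.frame, samples = data.frame).
simulateTrialImpl <- function(contrast, config, geometry, trialId, t0,
                              isRepeat = FALSE) {
  dt <- 1 / config$frameRate
  pR <- psychometricProb(contrast, config$psychometricSlope,
                         config$psychometricBias, config$lapseRate)
  choice <- if (stats::runif(1) < pR) "R" else "L"
  correct <- if (contrast > 0) choice == "R"
             else if (contrast < 0) choice == "L"
             else stats::runif(1) < 0.5   # zero contrast: either side, p = 0.5
  L <- geometry@corridorLength
  nMax <- ceiling(1.6 * L / (config$forwardSpeed * dt)) + 30L
  dz <- pmax(0.05 * config$forwardSpeed * dt,
             (config$forwardSpeed + stats::rnorm(nMax, 0, config$speedNoiseSd)) * dt)
  z <- geometry@zMin + cumsum(dz)
  nFrames <- which(z >= L)[1]
  if (is.na(nFrames)) nFrames <- nMax
  z <- z[seq_len(nFrames)]
  z[nFrames] <- L
  target <- if (choice == "R") config$thetaTarget else -config$thetaTarget
  rate <- config$headingDriftGain * (0.25 + abs(contrast))
  noise <- stats::rnorm(nFrames, 0, config$headingNoiseSd * sqrt(dt))
  theta <- numeric(nFrames)
  th <- 0
  for (k in seq_len(nFrames)) {
    ## commitment ramps with corridor progress: trajectories toward the two
    ## choices overlap early and diverge gradually along the corridor
    tgt <- target * min(1, z[k] / L)
    th <- th + rate * (tgt - th) * dt + noise[k]
    if (th > geometry@headingMax) th <- 2 * geometry@headingMax - th
    if (th < geometry@headingMin) th <- 2 * geometry@headingMin - th
    th <- min(max(th, geometry@headingMin), geometry@headingMax)
    theta[k] <- th
  }
  list(trial = data.frame(trialId = trialId, contrast = contrast,
                          choice = choice, correct = correct,
                          isRepeat = isRepeat),
       samples = data.frame(t = t0 + dt * seq_len(nFrames), trialId = trialId,
                            z = z, theta = theta))
}

#' Simulate a single trial
#'
#' Draws the choice from the psychometric model, then generates a bounded
#' drift-diffusion heading trajectory toward the chosen side and a
#' near-constant-speed advance along the corridor.
#'
#' @param contrast signed contrast in [-1, 1].
#' @param config a \code{\link{simulationConfig}}.
#' @param geometry a \code{\link{mazeGeometry}}.
#' @param trialId integer trial id.
#' @param t0 start of the trial on the global time base (s).
#' @param seed RNG seed for this trial.
#' @return list with elements \code{trial} (one-row data.frame) and
#'   \code{samples} (data.frame of t, trialId, z, theta).
#' @examples
#' tr <- simulateTrial(0.5, simulationConfig(), mazeGeometry(), seed = 1)
#' @export
simulateTrial <- function(contrast, config, geometry = mazeGeometry(),
                          trialId = 1L, t0 = 0, seed = config$seed) {
  stopIfNot(length(contrast) == 1 && abs(contrast) <= 1,
            "contrast must be a single value in [-1, 1]")
  withr::with_seed(as.integer(seed),
    simulateTrialImpl(contrast, config, geometry, trialId, t0))
}

#' Simulate a full behavioral session
#'
#' Contrasts are drawn uniformly from \code{config$contrastSet}. With baiting
#' enabled, each error trial is followed by repeats of the same stimulus
#' (flagged \code{isRepeat}) until answered correctly. Time is a single
#' global monotone base across trials, with an inter-trial gap containing no
#' samples.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param geometry a \code{\link{mazeGeometry}}.
#' @param maxRepeats safety cap on consecutive baited repeats of one
#'   stimulus.
#' @return A \code{\link{NavSession}} with zero neurons (attach activity with
#'   \code{\link{generateResponses}}).
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 12, seed = 1))
#' nTrials(sess)
#' @export
simulateSession <- function(config, geometry = mazeGeometry(),
                            maxRepeats = 25L) {
  stopIfNot(length(config$contrastSet) >= 1, "contrastSet must not be empty")
  withr::with_seed(config$seed, {
    contrasts <- sample(config$contrastSet, config$nTrials, replace = TRUE)
    trialList <- list()
    sampleList <- list()
    t0 <- 0
    id <- 0L
    for (k in seq_len(config$nTrials)) {
      id <- id + 1L
      tr <- simulateTrialImpl(contrasts[k], config, geometry, id, t0)
      trialList[[length(trialList) + 1L]] <- tr$trial
      sampleList[[length(sampleList) + 1L]] <- tr$samples
      t0 <- max(tr$samples$t) + config$interTrialInterval
      nRep <- 0L
      while (config$baitingEnabled && !tr$trial$correct && nRep < maxRepeats) {
        nRep <- nRep + 1L
        id <- id + 1L
        tr <- simulateTrialImpl(contrasts[k], config, geometry, id, t0,
                                isRepeat = TRUE)
        trialList[[length(trialList) + 1L]] <- tr$trial
        sampleList[[length(sampleList) + 1L]] <- tr$samples
        t0 <- max(tr$samples$t) + config$interTrialInterval
      }
    }
    navSession(do.call(rbind, trialList), do.call(rbind, sampleList),
               geometry = geometry, frameRate = config$frameRate)
  })
}

#' Generate a synthetic neural population
#'
#' Samples per-neuron ground-truth position-heading fields: unimodal Gaussian
#' bumps over (z, theta) with centers tiling the region of the maze the
#' trajectories actually reach (the reachable heading envelope widens with
#' z), plus additive-Gaussian observation noise with SD proportional to the
#' field amplitude. Each neuron's preferred choice is the side of its
#' preferred heading; \code{choiceGain < 1} makes the truth
#' decision-dependent by scaling the field on non-preferred-choice trials.
#'
#' @param nNeurons number of neurons (>= 1).
#' @param geometry a \code{\link{mazeGeometry}}.
#' @param seed RNG seed.
#' @param widthZRange,widthThetaRange ranges (cm, deg) for field widths.
#' @param amplitudeRange,baselineRange ranges (response units) for field
#'   amplitude and baseline.
#' @param noiseScale observation-noise SD as a fraction of amplitude.
#' @param choiceGain multiplicative field gain on trials ending in the
#'   neuron's non-preferred choice (1 = purely (z, theta)-tuned truth).
#' @return data.frame with one row per neuron: centerZ, centerTheta, widthZ,
#'   widthTheta, amplitude, baseline, sigma, prefChoice, choiceGain.
#' @examples
#' pop <- generatePopulation(5, seed = 1)
#' @export
generatePopulation <- function(nNeurons, geometry = mazeGeometry(), seed = 1,
                               widthZRange = c(8, 25),
                               widthThetaRange = c(10, 30),
                               amplitudeRange = c(0.5, 2),
                               baselineRange = c(0, 0.2),
                               noiseScale = 0.3,
                               choiceGain = 1) {
  stopIfNot(nNeurons >= 1, "nNeurons must be >= 1")
  withr::with_seed(as.integer(seed), {
    L <- geometry@corridorLength
    centerZ <- stats::runif(nNeurons, geometry@zMin + 0.05 * L, 0.95 * L)
    ## reachable heading envelope grows roughly linearly with z
    reach <- geometry@headingMax * (0.1 + 0.9 * centerZ / L)
    centerTheta <- stats::runif(nNeurons, -1, 1) * 0.8 * reach
    amplitude <- stats::runif(nNeurons, amplitudeRange[1], amplitudeRange[2])
    data.frame(
      neuron = seq_len(nNeurons),
      centerZ = centerZ,
      centerTheta = centerTheta,
      widthZ = stats::runif(nNeurons, widthZRange[1], widthZRange[2]),
      widthTheta = stats::runif(nNeurons, widthThetaRange[1], widthThetaRange[2]),
      amplitude = amplitude,
      baseline = stats::runif(nNeurons, baselineRange[1], baselineRange[2]),
      sigma = noiseScale * amplitude,
      prefChoice = ifelse(centerTheta >= 0, "R", "L"),
      choiceGain = rep_len(choiceGain, nNeurons))
  })
}

#' Evaluate a ground-truth field
#'
#' The simulator's tuning surface for one neuron:
#' baseline + gain * amplitude * exp(-(z - cz)^2 / (2 wz^2)
#' - (theta - ct)^2 / (2 wt^2)), with gain < 1 on non-preferred-choice
#' trials when the population is decision-dependent.
#'
#' @param neuron one row of a \code{\link{generatePopulation}} data.frame.
#' @param z,theta numeric vectors (recycled together).
#' @param choice optional per-sample choice ("L"/"R") for decision-dependent
#'   truths.
#' @return numeric vector of expected responses.
#' @export
truthFieldValue <- function(neuron, z, theta, choice = NULL) {
  gain <- 1
  if (!is.null(choice) && neuron$choiceGain != 1)
    gain <- ifelse(choice == neuron$prefChoice, 1, neuron$choiceGain)
  neuron$baseline + gain * neuron$amplitude *
    exp(-(z - neuron$centerZ)^2 / (2 * neuron$widthZ^2) -
          (theta - neuron$centerTheta)^2 / (2 * neuron$widthTheta^2))
}

#' Evaluate ground-truth fields on a grid
#'
#' @param population a \code{\link{generatePopulation}} data.frame.
#' @param grid a \code{\link{gridSpec}}.
#' @param choice optional single choice for decision-dependent truths.
#' @return list of z x theta matrices, one per neuron.
#' @export
truthFieldMatrix <- function(population, grid, choice = NULL) {
  zc <- zCenters(grid); tc <- thetaCenters(grid)
  zz <- matrix(zc, length(zc), length(tc))
  tt <- matrix(tc, length(zc), length(tc), byrow = TRUE)
  lapply(seq_len(nrow(population)), function(i) {
    ch <- if (is.null(choice)) NULL else rep(choice, length(zz))
    matrix(truthFieldValue(population[i, ], as.vector(zz), as.vector(tt), ch),
           length(zc), length(tc))
  })
}

#' Generate neural responses along a session's trajectory
#'
#' For each neuron i and frame t, r_i(t) = mu_i(z(t), theta(t)) + eps_i(t)
#' with eps_i(t) ~ Normal(0, sigma_i), matching the Gaussian response model
#' assumed by the decoder. An optional calcium-impulse-response convolution
#' (exponential kernel) exists for robustness experiments and is off by
#' default, because the field and decoding models are defined on
#' instantaneous responses.
#'
#' @param session a \code{\link{NavSession}}.
#' @param population a \code{\link{generatePopulation}} data.frame.
#' @param seed RNG seed.
#' @param calciumKernel if TRUE, convolve each trace with a causal
#'   exponential kernel of time constant \code{kernelTau} (per trial).
#' @param kernelTau decay time constant in seconds.
#' @return the session with the \code{"response"} assay filled (neurons x
#'   frames) and the population stored in \code{metadata}.
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 12, seed = 1))
#' sess <- generateResponses(sess, generatePopulation(4, seed = 2), seed = 3)
#' dim(responses(sess))
#' @export
generateResponses <- function(session, population, seed = 1,
                              calciumKernel = FALSE, kernelTau = 0.5) {
  stopIfNot(nrow(population) >= 1, "population must not be empty")
  traj <- trajectory(session)
  ch <- frameChoice(session)
  nFrames <- nrow(traj)
  withr::with_seed(as.integer(seed), {
    R <- matrix(0, nrow(population), nFrames,
                dimnames = list(paste0("neuron_", population$neuron), NULL))
    for (i in seq_len(nrow(population))) {
      mu <- truthFieldValue(population[i, ], traj$z, traj$theta, ch)
      R[i, ] <- mu + stats::rnorm(nFrames, 0, population$sigma[i])
    }
    if (calciumKernel) {
      dt <- 1 / frameRate(session)
      a <- exp(-dt / kernelTau)
      for (id in unique(traj$trialId)) {
        idx <- which(traj$trialId == id)
        R[, idx] <- t(apply(R[, idx, drop = FALSE], 1, function(x)
          as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))))
      }
    }
    navSession(trials(session), traj, responses = R,
               geometry = geometry(session), frameRate = frameRate(session),
               population = population)
  })
}

#' Convert raw fluorescence to Delta F / F
#'
#' Computes (F - F0) / F0 with the baseline F0 taken as the 20th percentile
#' of the whole trace (linear-interpolation percentile convention).
#'
#' @param raw numeric vector (one trace) or matrix (neurons x frames) of
#'   positive raw fluorescence values.
#' @param probs baseline percentile (default 0.2).
#' @return object of the same shape with Delta F / F values.
#' @examples
#' computeDff(c(10, 12, 20, 11, 15))
#' @export
computeDff <- function(raw, probs = 0.2) {
  one <- function(x) {
    stopIfNot(all(is.finite(x)), "trace must be finite")
    f0 <- stats::quantile(x, probs, type = 7, names = FALSE)
    if (f0 <= 0)
      stop("degenerate baseline: F0 = ", f0, " is not positive")
    (x - f0) / f0
  }
  if (is.matrix(raw)) t(apply(raw, 1, one)) else one(raw)
}
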