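## Shared fixtures, generated in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

smallSession <- function(nTrials = 60, seed = 7) {
  fixture(paste0("sess_", nTrials, "_", seed), function()
    simulateSession(simulationConfig(nTrials = nTrials, seed = seed)))
}

## a hand-built session whose frames sit at chosen (z, theta) positions
manualSession <- function(frames, choices = NULL, contrasts = NULL) {
  ids <- unique(frames$trialId)
  if (is.null(choices)) choices <- rep(c("L", "R"), length.out = length(ids))
  if (is.null(contrasts)) contrasts <- rep(0, length(ids))
  trials <- data.frame(trialId = ids, contrast = contrasts, choice = choices,
                       correct = TRUE, isRepeat = FALSE)
  navSession(trials, frames)
}

## neurons with specified truth parameters
manualPopulation <- function(centerZ, centerTheta, widthZ, widthTheta,
                             amplitude = 1, baseline = 0, sigma = 0,
                             choiceGain = 1) {
  n <- length(centerZ)
  data.frame(neuron = seq_len(n), centerZ = centerZ,
             centerTheta = centerTheta,
             widthZ = rep_len(widthZ, n), widthTheta = rep_len(widthTheta, n),
             amplitude = rep_len(amplitude, n),
             baseline = rep_len(baseline, n), sigma = rep_len(sigma, n),
             prefChoice = ifelse(centerTheta >= 0, "R", "L"),
             choiceGain = rep_len(choiceGain, n))
}
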