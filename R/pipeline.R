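## End-to-end driver: simulate -> fields -> compare -> decode -> behavior,
## with a single master seed that determines every stochastic stage.

#' Pipeline run configuration
#'
#' Bundles the configuration of every stage. The master seed fully
#' determines the run: each stochastic stage (simulation, population,
#' responses, fold assignment, classifier folds) receives a derived child
#' seed, so two runs from the same configuration are byte-identical apart
#' from wall-clock entries in the manifest.
#'
#' @param simulation a \code{\link{simulationConfig}} (its seed is
#'   overridden by a child of \code{masterSeed}).
#' @param nNeurons size of the synthetic population.
#' @param geometry a \code{\link{mazeGeometry}}.
#' @param gridZStep,gridThetaStep analysis grid resolution (cm, deg).
#' @param estimator an \code{\link{estimatorConfig}} (fold seed overridden).
#' @param aurocThreshold exclusion threshold for the model comparison.
#' @param checkpoints position checkpoints (cm) for the behavioral and
#'   neurometric analyses.
#' @param noiseScale,choiceGain population parameters passed to
#'   \code{\link{generatePopulation}}.
#' @param masterSeed integer master seed.
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      nNeurons = 25,
                      geometry = mazeGeometry(),
                      gridZStep = 2, gridThetaStep = 3,
                      estimator = estimatorConfig(),
                      aurocThreshold = 0.95,
                      checkpoints = c(20, 40, 60, 80, 100),
                      noiseScale = 0.3, choiceGain = 1,
                      masterSeed = 1) {
  problems <- character(0)
  if (!inherits(simulation, "SimulationConfig"))
    problems <- c(problems, "simulation must be a simulationConfig()")
  if (length(nNeurons) != 1 || nNeurons < 1)
    problems <- c(problems, "nNeurons must be >= 1")
  if (!is(geometry, "MazeGeometry"))
    problems <- c(problems, "geometry must be a mazeGeometry()")
  if (gridZStep <= 0 || gridThetaStep <= 0)
    problems <- c(problems, "grid steps must be positive")
  if (!inherits(estimator, "EstimatorConfig"))
    problems <- c(problems, "estimator must be an estimatorConfig()")
  if (aurocThreshold <= 0.5 || aurocThreshold > 1)
    problems <- c(problems, "aurocThreshold must be in (0.5, 1]")
  if (!length(checkpoints) || any(checkpoints <= 0) ||
      any(checkpoints > geometry@corridorLength))
    problems <- c(problems, "checkpoints must lie inside the corridor")
  if (length(problems))
    stop("invalid RunConfig:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(list(simulation = simulation, nNeurons = as.integer(nNeurons),
                 geometry = geometry, gridZStep = gridZStep,
                 gridThetaStep = gridThetaStep, estimator = estimator,
                 aurocThreshold = aurocThreshold, checkpoints = checkpoints,
                 noiseScale = noiseScale, choiceGain = choiceGain,
                 masterSeed = as.integer(masterSeed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Simulates a session and population, estimates per-neuron tuning fields
#' with cross-validated bandwidths, compares the three response models under
#' the auROC exclusion mask, decodes the trajectory with the leave-one-trial-
#' out Bayesian decoder, runs the behavioral and neurometric analyses, and
#' writes every report to \code{outDir} (session files under
#' \code{session/}, then \code{fields.json}, \code{model_report.json},
#' \code{exclusion.csv}, sequence CSVs, \code{decoded.csv},
#' \code{neurometric.json}, \code{behavior_report.json} and a
#' \code{manifest.json} with seeds and per-stage wall times).
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory.
#' @param verbose print stage progress?
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, outDir, verbose = FALSE) {
  stopIfNot(inherits(config, "RunConfig"), "config must be a runConfig()")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulation = childSeed(config$masterSeed, 1),
                population = childSeed(config$masterSeed, 2),
                responses = childSeed(config$masterSeed, 3),
                folds = childSeed(config$masterSeed, 4),
                classifier = childSeed(config$masterSeed, 5))
  times <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    if (verbose) message("[", name, "] ...")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## simulate ---------------------------------------------------------------
  sim <- config$simulation
  sim$seed <- seeds$simulation
  est <- config$estimator
  est$foldSeed <- seeds$folds
  grid <- defaultGrid(config$geometry, config$gridZStep, config$gridThetaStep)
  session <- stage("simulate", {
    s <- simulateSession(sim, config$geometry)
    pop <- generatePopulation(config$nNeurons, config$geometry,
                              seed = seeds$population,
                              noiseScale = config$noiseScale,
                              choiceGain = config$choiceGain)
    s <- generateResponses(s, pop, seed = seeds$responses)
    writeSession(s, file.path(outDir, "session"))
    s
  })

  ## fields -----------------------------------------------------------------
  fieldFits <- stage("fields", {
    R <- responses(session)
    fits <- lapply(seq_len(nrow(R)), function(i)
      selectBandwidths(session, R[i, ], grid, est))
    writeJson(fieldsToJson(fits, grid), file.path(outDir, "fields.json"))
    fits
  })

  ## compare ----------------------------------------------------------------
  report <- stage("compare", {
    rep <- compareModels(session, grid, est,
                         aurocThreshold = config$aurocThreshold,
                         returnPredictions = TRUE)
    seqActual <- buildChoiceSequences(session, responses(session))
    seqPred <- buildChoiceSequences(session, rep$predictions$zt,
                                    ordering = seqActual$ordering)
    peakRankCor <- stats::cor(seqActual$ordering$peakBin,
                              seqPred$ordering$peakBin, method = "spearman")
    writeJson(list(per_neuron = rep$perNeuron, summary = rep$summary,
                   n_undefined = rep$nUndefined,
                   sequence_peak_rank_correlation = peakRankCor),
              file.path(outDir, "model_report.json"))
    maskToCsv(rep$mask, file.path(outDir, "exclusion.csv"))
    sequencesToCsv(seqActual, file.path(outDir, "sequences_actual"))
    sequencesToCsv(seqPred, file.path(outDir, "sequences_predicted"))
    c(rep, list(peakRankCor = peakRankCor))
  })

  ## decode -----------------------------------------------------------------
  decoded <- stage("decode", {
    dec <- decodeSession(session, grid, est,
                         fieldBw = lapply(fieldFits, `[[`, "bandwidths"))
    writeCsv(data.frame(frame = dec$decoded$frame,
                        trial_id = dec$decoded$trialId,
                        z_true = dec$decoded$zTrue,
                        theta_true = dec$decoded$thetaTrue,
                        z_map = dec$decoded$zMap,
                        theta_map = dec$decoded$thetaMap,
                        log_post_max = dec$decoded$logPostMax),
             file.path(outDir, "decoded.csv"))
    nm <- neurometricChoice(dec, session, config$checkpoints,
                            seed = seeds$classifier)
    writeJson(list(curve = nm$curve, neurometric = nm$neurometric,
                   mean_abs_diff = as.list(nm$meanAbsDiff)),
              file.path(outDir, "neurometric.json"))
    list(decode = dec, neurometric = nm)
  })

  ## behavior ---------------------------------------------------------------
  behavior <- stage("behavior", {
    psy <- psychometric(session)
    hp <- headingChoicePredictability(session, config$checkpoints,
                                      seed = seeds$classifier)
    cp <- conditionalPsychometric(session, config$checkpoints,
                                  seed = seeds$classifier)
    writeJson(list(psychometric = list(points = psy$points, fit = psy$fit),
                   predictability = hp$curve,
                   conditional = cp$byCheckpoint,
                   conditional_mean_abs_diff = as.list(cp$meanAbsDiff)),
              file.path(outDir, "behavior_report.json"))
    list(psychometric = psy, predictability = hp, conditional = cp)
  })

  writeJson(list(package_version = as.character(utils::packageVersion("navfield")),
                 master_seed = config$masterSeed, seeds = seeds,
                 n_trials = nTrials(session), n_neurons = nNeurons(session),
                 stage_seconds = times),
            file.path(outDir, "manifest.json"))
  invisible(list(session = session, fields = fieldFits, report = report,
                 decoded = decoded, behavior = behavior, seeds = seeds))
}
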