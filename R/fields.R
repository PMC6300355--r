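## Occupancy-regularized tuning-field estimation and cross-validated
## bandwidth selection.

#' Default bandwidth candidate grid
#'
#' Log-spaced candidates covering sub-bin to field-scale smoothing.
#'
#' @param sigmaZ,sigmaTheta candidate bandwidths (cm, deg).
#' @return data.frame with columns sigmaZ, sigmaTheta (all combinations).
#' @export
defaultBandwidthGrid <- function(sigmaZ = c(2, 4, 8, 16, 32),
                                 sigmaTheta = c(3, 6, 12, 24, 45)) {
  expand.grid(sigmaZ = sigmaZ, sigmaTheta = sigmaTheta,
              KEEP.OUT.ATTRS = FALSE)
}

#' Field-estimator configuration
#'
#' @param lambda occupancy-count regularizer (> 0); keeps the ratio estimate
#'   finite and pulls it toward the mean response where occupancy is low.
#' @param bandwidthCandidates data.frame of candidate (sigmaZ, sigmaTheta)
#'   pairs, as from \code{\link{defaultBandwidthGrid}}.
#' @param nFolds number of cross-validation folds (trials are the CV unit).
#' @param foldSeed seed for the fold assignment.
#' @param lookupMethod "bilinear" or "nearest" field lookup along the
#'   trajectory when computing the cross-validation error.
#' @return A validated list of class \code{"EstimatorConfig"}.
#' @export
estimatorConfig <- function(lambda = 1,
                            bandwidthCandidates = defaultBandwidthGrid(),
                            nFolds = 10, foldSeed = 1,
                            lookupMethod = "bilinear") {
  stopIfNot(lambda > 0, "lambda must be positive")
  stopIfNot(nrow(bandwidthCandidates) >= 1, "candidate list must not be empty")
  stopIfNot(all(c("sigmaZ", "sigmaTheta") %in% names(bandwidthCandidates)),
            "candidates need sigmaZ and sigmaTheta columns")
  stopIfNot(all(bandwidthCandidates$sigmaZ > 0) &&
              all(bandwidthCandidates$sigmaTheta > 0),
            "bandwidth candidates must be positive")
  stopIfNot(nFolds >= 2, "nFolds must be >= 2")
  structure(list(lambda = lambda,
                 bandwidthCandidates = bandwidthCandidates,
                 nFolds = as.integer(nFolds), foldSeed = as.integer(foldSeed),
                 lookupMethod = match.arg(lookupMethod,
                                          c("bilinear", "nearest"))),
            class = "EstimatorConfig")
}

#' Estimate a tuning field from binned maps
#'
#' The regularized smoothed-ratio estimator: both maps are filtered with the
#' same Gaussian kernel and the field is
#' \code{(M_sig_filt + lambda * fMean) / (M_occ_filt + lambda)}.
#' With \code{lambda > 0} the ratio is finite everywhere and tends to
#' \code{fMean} in bins with no smoothed occupancy.
#'
#' @param maps a \code{\link{BinnedMaps}} object.
#' @param bw a \code{\link{bandwidths}} object.
#' @param lambda positive regularizer (occupancy-count units).
#' @param fMean the neuron's mean response over the contributing frames.
#' @param trainedTrials optional integer trial ids the maps came from
#'   (recorded for the cross-validation contract).
#' @return A \code{\link{FieldEstimate}}.
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 10, seed = 1))
#' tr <- rnorm(ncol(sess))
#' maps <- binTrajectory(sess, tr, defaultGrid())
#' estimateField(maps, bandwidths(8, 12), 1, mean(tr))
#' @export
estimateField <- function(maps, bw, lambda, fMean, trainedTrials = integer(0)) {
  stopIfNot(lambda > 0, "lambda must be positive")
  occF <- smoothMap(maps@occupancy, maps@grid, bw)
  sigF <- smoothMap(maps@signal, maps@grid, bw)
  new("FieldEstimate", values = (sigF + lambda * fMean) / (occF + lambda),
      grid = maps@grid, bandwidths = bw, lambda = lambda, fMean = fMean,
      trainedTrials = as.integer(trainedTrials))
}

#' Cross-validation error of a field on held-out frames
#'
#' The dimensionless error
#' \code{eps = <(Fhat(z(t), theta(t)) - F(t))^2> / <(F(t) - fMeanTrain)^2>},
#' i.e. mean squared prediction error over the test frames normalized by the
#' mean squared deviation of the test trace from the training mean.
#'
#' @param session a \code{\link{NavSession}}.
#' @param trace response vector aligned with the session frames.
#' @param frames logical or integer index of the held-out (test) frames.
#' @param field a \code{\link{FieldEstimate}} fit without those frames.
#' @param fMeanTrain mean response of the training subset.
#' @param method field lookup method along the trajectory.
#' @return the scalar error eps.
#' @export
cvErrorTrace <- function(session, trace, frames, field, fMeanTrain,
                         method = "bilinear") {
  traj <- trajectory(session)
  sel <- seq_len(nrow(traj))[frames]
  r <- trace[sel]
  den <- mean((r - fMeanTrain)^2)
  if (den == 0)
    stop("degenerate test set: constant trace, error undefined")
  pred <- fieldLookup(field, traj$z[sel], traj$theta[sel], method = method)
  mean((pred - r)^2) / den
}

## Shared fast path for bandwidth selection: precompute per-fold maps and
## interpolation weights once, then sweep the candidate grid.
##
## Returns list(bandwidths, field, cvTable, folds, trialIds).
selectBandwidthsImpl <- function(session, trace, grid, config,
                                 trialSubset = NULL) {
  tr <- trials(session)
  if (!is.null(trialSubset)) tr <- tr[tr$trialId %in% trialSubset, ]
  if (nrow(tr) < config$nFolds)
    stop("need at least ", config$nFolds, " trials (got ", nrow(tr), ")")
  fold <- makeFolds(tr$choice, config$nFolds, config$foldSeed)
  traj <- trajectory(session)
  inScope <- traj$trialId %in% tr$trialId
  total <- binTrajectory(session, trace, grid, frameMask = inScope)
  lambda <- config$lambda
  d <- gridDim(grid)
  dz <- uniformStep(grid@zEdges, "z")
  dtt <- uniformStep(grid@thetaEdges, "theta")

  foldData <- lapply(seq_len(config$nFolds), function(f) {
    testTrials <- tr$trialId[fold == f]
    testMask <- traj$trialId %in% testTrials
    testMaps <- binTrajectory(session, trace, grid, frameMask = testMask)
    trainOcc <- total@occupancy - testMaps@occupancy
    trainSig <- total@signal - testMaps@signal
    nTrain <- sum(trainOcc)
    fMeanTrain <- sum(trainSig) / nTrain
    sel <- which(testMask)
    r <- trace[sel]
    den <- mean((r - fMeanTrain)^2)
    if (den == 0)
      stop("degenerate test fold: constant trace, error undefined")
    list(trainOcc = trainOcc, trainSig = trainSig, fMeanTrain = fMeanTrain,
         r = r, den = den,
         w = if (config$lookupMethod == "bilinear")
               interpWeights(grid, traj$z[sel], traj$theta[sel])
             else frameBins(grid,
                            pmin(pmax(traj$z[sel], min(grid@zEdges)), max(grid@zEdges)),
                            pmin(pmax(traj$theta[sel], min(grid@thetaEdges)), max(grid@thetaEdges))))
  })

  cand <- config$bandwidthCandidates
  Kzs <- lapply(unique(cand$sigmaZ), function(s) gaussKernelMatrix(d[1], s / dz))
  names(Kzs) <- as.character(unique(cand$sigmaZ))
  Kts <- lapply(unique(cand$sigmaTheta), function(s) gaussKernelMatrix(d[2], s / dtt))
  names(Kts) <- as.character(unique(cand$sigmaTheta))

  eps <- vapply(seq_len(nrow(cand)), function(ci) {
    Kz <- Kzs[[as.character(cand$sigmaZ[ci])]]
    Kt <- Kts[[as.character(cand$sigmaTheta[ci])]]
    mean(vapply(foldData, function(fd) {
      occF <- Kz %*% fd$trainOcc %*% t(Kt)
      sigF <- Kz %*% fd$trainSig %*% t(Kt)
      values <- (sigF + lambda * fd$fMeanTrain) / (occF + lambda)
      pred <- if (config$lookupMethod == "bilinear") applyInterp(values, fd$w)
              else values[cbind(fd$w$iz, fd$w$it)]
      mean((pred - fd$r)^2) / fd$den
    }, numeric(1)))
  }, numeric(1))

  ## argmin; ties broken toward the largest sigmaZ, then sigmaTheta
  best <- which(eps == min(eps))
  best <- best[order(cand$sigmaZ[best], cand$sigmaTheta[best],
                     decreasing = TRUE)][1]
  bw <- bandwidths(cand$sigmaZ[best], cand$sigmaTheta[best])
  fMeanAll <- sum(total@signal) / sum(total@occupancy)
  field <- estimateField(total, bw, lambda, fMeanAll,
                         trainedTrials = tr$trialId)
  field@cvError <- eps[best]
  list(bandwidths = bw, field = field,
       cvTable = cbind(cand, epsilon = eps), folds = fold,
       trialIds = tr$trialId)
}

#' Select smoothing bandwidths by cross-validation
#'
#' Trials are partitioned into \code{nFolds} choice-balanced groups; for each
#' candidate (sigmaZ, sigmaTheta) the field is estimated from 90% of the
#' trials and scored on the held-out 10% with the normalized error
#' \code{\link{cvErrorTrace}}, averaged over folds. The candidate with the
#' lowest mean error wins (ties broken toward larger bandwidths, which
#' generalize better at equal measured error), and the field is refit on all
#' trials at the winning bandwidths.
#'
#' @param session a \code{\link{NavSession}}.
#' @param trace response vector aligned with the session frames.
#' @param grid a \code{\link{gridSpec}}.
#' @param config an \code{\link{estimatorConfig}}.
#' @param trialSubset optional trial ids to restrict to (used by the
#'   choice-conditioned models).
#' @return list with elements \code{bandwidths} (the winner), \code{field}
#'   (refit on all trials, with \code{cvError} set), and \code{cvTable}
#'   (per-candidate mean error).
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 20, seed = 1))
#' pop <- generatePopulation(1, seed = 2)
#' sess <- generateResponses(sess, pop, seed = 3)
#' fit <- selectBandwidths(sess, responses(sess)[1, ], defaultGrid(),
#'                         estimatorConfig(nFolds = 5))
#' fit$bandwidths
#' @export
selectBandwidths <- function(session, trace, grid, config = estimatorConfig(),
                             trialSubset = NULL) {
  res <- selectBandwidthsImpl(session, trace, grid, config, trialSubset)
  res[c("bandwidths", "field", "cvTable")]
}
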