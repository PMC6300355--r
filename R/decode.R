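## Grid-based Bayesian decoding of (z, theta) from population activity under
## a Gaussian response model, with an occupancy prior and leave-one-trial-out
## field estimation, plus the neurometric choice analysis.

#' Per-neuron response noise for the decoder
#'
#' The decoder's sigma_i: the standard deviation of the neuron's response
#' over the whole session (population 1/n variance convention). A floor of
#' \code{floorFactor * range(trace)} (or \code{floorFactor} itself for a
#' constant trace) avoids a degenerate zero-width likelihood.
#'
#' @param trace numeric response vector.
#' @param floorFactor relative floor on sigma.
#' @return list: \code{sigma} and logical \code{floored}.
#' @examples
#' estimateSigmaI(c(0, 2))$sigma  # 1
#' @export
estimateSigmaI <- function(trace, floorFactor = 1e-6) {
  stopIfNot(length(trace) >= 2, "need at least 2 frames")
  s <- sqrt(mean((trace - mean(trace))^2))
  floor <- floorFactor * diff(range(trace))
  if (floor == 0) floor <- floorFactor
  list(sigma = max(s, floor), floored = s < floor)
}

#' Occupancy prior over the position-heading grid
#'
#' Smoothed, normalized occupancy of the (training) frames: the decoder's
#' Pr(z, theta). Bins with zero smoothed occupancy receive a small
#' epsilon-mass before normalization so the log prior is finite.
#'
#' @param session a \code{\link{NavSession}}.
#' @param grid a \code{\link{gridSpec}}.
#' @param bw smoothing \code{\link{bandwidths}} for the occupancy map.
#' @param frameMask optional frame subset (training frames).
#' @param eps mass given to empty bins before normalization.
#' @return matrix of per-bin probabilities (sums to 1).
#' @export
occupancyPrior <- function(session, grid, bw = bandwidths(4, 6),
                           frameMask = NULL, eps = 1e-8) {
  occ <- binTrajectory(session, rep(0, ncol(session)), grid,
                       frameMask = frameMask)@occupancy
  P <- smoothMap(occ, grid, bw)
  P[P <= 0] <- eps
  P / sum(P)
}

## z-outer (theta-fastest) linearization used for MAP tie-breaking.
linearizeZOuter <- function(M) as.vector(t(M))

#' Log-posterior over the grid for one population response
#'
#' Evaluates, up to an additive constant,
#' \code{log Post(z, theta) = -sum_i (mu_i(z, theta) - r_i)^2 / (2 sigma_i^2)
#' + log Pr(z, theta)}. The MAP is the argmax bin, ties broken toward the
#' first bin in z-outer (theta-fastest) order.
#'
#' @param response numeric vector, one response per neuron.
#' @param fields list of per-neuron \code{\link{FieldEstimate}}s (or plain
#'   matrices) on one shared grid, acting as mu_i.
#' @param sigmas per-neuron noise SDs (> 0).
#' @param prior probability matrix over the grid (a \code{\link{occupancyPrior}});
#'   bins with zero prior get log-posterior -Inf.
#' @param grid required when \code{fields} are plain matrices.
#' @return list: \code{logPost} (matrix over the grid), \code{mapBin}
#'   (c(iz, itheta)), and \code{map} (c(z, theta) bin centers).
#' @export
logPosterior <- function(response, fields, sigmas, prior, grid = NULL) {
  stopIfNot(length(fields) == length(response) &&
              length(sigmas) == length(response),
            "response, fields and sigmas must have one entry per neuron")
  stopIfNot(all(sigmas > 0), "sigmas must be positive")
  if (length(fields) && is(fields[[1]], "FieldEstimate")) {
    grid <- fields[[1]]@grid
    fields <- lapply(fields, fieldValues)
  }
  stopIfNot(!is.null(grid), "grid must be supplied for plain matrices")
  d <- gridDim(grid)
  ll <- matrix(0, d[1], d[2])
  for (i in seq_along(fields))
    ll <- ll - (fields[[i]] - response[i])^2 / (2 * sigmas[i]^2)
  logPost <- ll + log(prior)
  v <- linearizeZOuter(logPost)
  k <- which.max(v)
  iz <- (k - 1L) %/% d[2] + 1L
  it <- (k - 1L) %% d[2] + 1L
  list(logPost = logPost, mapBin = c(iz = iz, itheta = it),
       map = c(z = zCenters(grid)[iz], theta = thetaCenters(grid)[it]))
}

#' Decode a session's trajectory from population activity
#'
#' Leave-one-trial-out Bayesian MAP decoding: for each trial, every neuron's
#' tuning field mu_i and the occupancy prior are re-estimated from all other
#' trials, and each frame of the held-out trial is decoded by maximizing the
#' Gaussian log-posterior over the grid. Smoothing bandwidths are selected
#' once per neuron on the full session and reused across the per-trial
#' refits; sigma_i is the full-session response SD.
#'
#' @param session a \code{\link{NavSession}} with at least one neuron and
#'   two trials.
#' @param grid a \code{\link{gridSpec}}.
#' @param config an \code{\link{estimatorConfig}} for bandwidth selection.
#' @param priorBw occupancy-prior smoothing bandwidths.
#' @param fieldBw optional fixed \code{\link{bandwidths}} (single object or
#'   per-neuron list) to skip selection.
#' @param sigmas optional per-neuron noise SDs overriding the full-session
#'   estimate (e.g. noise estimates from an external preprocessing step).
#' @param includeOwnTrial if TRUE, fields are estimated from all trials
#'   including the decoded one (deliberately violating the cross-validation
#'   contract; only for diagnosing how much the bookkeeping matters).
#' @return list of class \code{"DecodedTrajectory"}: \code{decoded}
#'   (data.frame frame, trialId, zTrue, thetaTrue, zMap, thetaMap,
#'   logPostMax), \code{sigmas}, \code{bandwidths}, \code{grid}.
#' @export
decodeSession <- function(session, grid = defaultGrid(geometry(session)),
                          config = estimatorConfig(),
                          priorBw = bandwidths(4, 6), fieldBw = NULL,
                          sigmas = NULL, includeOwnTrial = FALSE) {
  R <- responses(session)
  stopIfNot(nrow(R) >= 1, "session must contain at least one neuron")
  tr <- trials(session)
  stopIfNot(nrow(tr) >= 2, "leave-one-trial-out needs at least 2 trials")
  traj <- trajectory(session)
  nN <- nrow(R); nFrames <- nrow(traj)
  d <- gridDim(grid); nz <- d[1]; nt <- d[2]; nBins <- nz * nt
  lambda <- config$lambda

  sig <- lapply(seq_len(nN), function(i) estimateSigmaI(R[i, ]))
  if (is.null(sigmas)) sigmas <- vapply(sig, `[[`, numeric(1), "sigma")
  stopIfNot(length(sigmas) == nN && all(sigmas > 0),
            "sigmas must be one positive value per neuron")

  if (is.null(fieldBw)) {
    bwList <- lapply(seq_len(nN), function(i)
      selectBandwidths(session, R[i, ], grid, config)$bandwidths)
  } else if (is(fieldBw, "Bandwidths")) {
    bwList <- rep(list(fieldBw), nN)
  } else bwList <- fieldBw
  bwKey <- vapply(bwList, function(b) paste(b@sigmaZ, b@sigmaTheta),
                  character(1))

  ## binned totals in z-outer (theta-fastest) linear order
  b <- frameBins(grid, traj$z, traj$theta)
  lin <- (b$iz - 1L) * nt + b$it
  totalOcc <- tabulate(lin, nBins)
  totalSig <- matrix(0, nBins, nN)
  sums <- rowsum(t(R), lin)
  totalSig[as.integer(rownames(sums)), ] <- sums
  rowTotals <- rowSums(R)

  toMatrix <- function(v) t(matrix(v, nt, nz))
  dz <- uniformStep(grid@zEdges, "z")
  dtt <- uniformStep(grid@thetaEdges, "theta")
  KzP <- gaussKernelMatrix(nz, priorBw@sigmaZ / dz)
  KtP <- gaussKernelMatrix(nt, priorBw@sigmaTheta / dtt)

  out <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    idx <- which(traj$trialId == tr$trialId[k])
    if (includeOwnTrial) {
      trainOcc <- totalOcc
      trainSig <- totalSig
      nTrain <- nFrames
      fMeans <- rowTotals / nTrain
    } else {
      linK <- lin[idx]
      occK <- tabulate(linK, nBins)
      sigK <- matrix(0, nBins, nN)
      sK <- rowsum(t(R[, idx, drop = FALSE]), linK)
      sigK[as.integer(rownames(sK)), ] <- sK
      trainOcc <- totalOcc - occK
      trainSig <- totalSig - sigK
      nTrain <- nFrames - length(idx)
      fMeans <- (rowTotals - rowSums(R[, idx, drop = FALSE])) / nTrain
    }
    occM <- toMatrix(trainOcc)
    P <- KzP %*% occM %*% t(KtP)
    P[P <= 0] <- 1e-8
    logPrior <- linearizeZOuter(log(P / sum(P)))

    B <- matrix(0, nBins, nN)
    for (key in unique(bwKey)) {
      neurons <- which(bwKey == key)
      bw <- bwList[[neurons[1]]]
      Kz <- gaussKernelMatrix(nz, bw@sigmaZ / dz)
      Kt <- gaussKernelMatrix(nt, bw@sigmaTheta / dtt)
      occF <- linearizeZOuter(Kz %*% occM %*% t(Kt))
      for (i in neurons) {
        sigF <- linearizeZOuter(Kz %*% toMatrix(trainSig[, i]) %*% t(Kt))
        B[, i] <- (sigF + lambda * fMeans[i]) / (occF + lambda)
      }
    }
    Rk <- R[, idx, drop = FALSE]
    invV <- 1 / (2 * sigmas^2)
    term1 <- as.vector(B^2 %*% invV)
    term2 <- B %*% (Rk * (2 * invV))
    term3 <- as.vector(invV %*% Rk^2)
    lp <- sweep(term2 - term1 + logPrior, 2, term3)
    mapIdx <- max.col(t(lp), ties.method = "first")
    iz <- (mapIdx - 1L) %/% nt + 1L
    it <- (mapIdx - 1L) %% nt + 1L
    out[[k]] <- data.frame(
      frame = idx, trialId = tr$trialId[k],
      zTrue = traj$z[idx], thetaTrue = traj$theta[idx],
      zMap = zCenters(grid)[iz], thetaMap = thetaCenters(grid)[it],
      logPostMax = lp[cbind(mapIdx, seq_along(idx))])
  }
  decoded <- do.call(rbind, out)
  decoded <- decoded[order(decoded$frame), ]
  rownames(decoded) <- NULL
  structure(list(decoded = decoded, sigmas = sigmas, bandwidths = bwList,
                 grid = grid,
                 sigmaFloored = vapply(sig, `[[`, logical(1), "floored")),
            class = "DecodedTrajectory")
}

#' @export
print.DecodedTrajectory <- function(x, ...) {
  cat("DecodedTrajectory:", nrow(x$decoded), "frames,",
      length(x$sigmas), "neurons\n")
  cat(sprintf("median |z error| = %.2f cm, median |theta error| = %.2f deg\n",
              stats::median(abs(x$decoded$zMap - x$decoded$zTrue)),
              stats::median(abs(x$decoded$thetaMap - x$decoded$thetaTrue))))
  invisible(x)
}

#' Neurometric choice analysis of a decoded trajectory
#'
#' Feeds the decoded heading at each trial's first crossing of every
#' checkpoint into the identical cross-validated threshold classifier used
#' for the behavioral heading analysis, yielding neurometric choice
#' predictability as a function of position and per-contrast neurometric
#' curves. With a perfect decoder (decoded heading equal to the actual
#' heading) the result equals the behavioral curves exactly.
#'
#' @param decoded a \code{\link{decodeSession}} result.
#' @param session the decoded \code{\link{NavSession}}.
#' @param zCheckpoints positions (cm).
#' @param nFolds,seed classifier cross-validation settings.
#' @return list of class \code{"NeurometricResult"}: \code{curve}
#'   (predictability vs z), \code{neurometric} (per-checkpoint per-contrast
#'   predicted-rightward fractions), \code{meanAbsDiff} vs the actual
#'   psychometric points.
#' @export
neurometricChoice <- function(decoded, session, zCheckpoints, nFolds = 10,
                              seed = 1) {
  dec <- decoded$decoded
  stopIfNot(nrow(dec) == ncol(session),
            "decoded trajectory must cover every session frame")
  thetaHat <- dec$thetaMap[order(dec$frame)]
  hp <- headingChoicePredictability(session, zCheckpoints, nFolds, seed,
                                    thetaSource = thetaHat)
  cp <- conditionalPsychometric(session, zCheckpoints, nFolds, seed,
                                thetaSource = thetaHat)
  structure(list(curve = hp$curve, neurometric = cp$byCheckpoint,
                 meanAbsDiff = cp$meanAbsDiff, actual = cp$actual),
            class = "NeurometricResult")
}
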