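## Nested response models f(z,theta), f(z,d), f(z,theta,d): fitting,
## cross-validated prediction, auROC-based confound exclusion, quality
## scoring, and choice-conditioned activation sequences.

## Candidate grid for the theta-marginal (1-D in z) model: the 2-D machinery
## is reused on the same z axis with a 2-bin theta axis smoothed by an
## effectively infinite sigmaTheta, so the prediction is flat in theta
## within each choice class and only sigmaZ is cross-validated.
flatThetaSigma <- 1e6

marginalGrid <- function(grid) {
  e <- grid@thetaEdges
  gridSpec(grid@zEdges, c(min(e), mean(range(e)), max(e)))
}

marginalConfig <- function(config) {
  estimatorConfig(lambda = config$lambda,
                  bandwidthCandidates = data.frame(
                    sigmaZ = unique(config$bandwidthCandidates$sigmaZ),
                    sigmaTheta = flatThetaSigma),
                  nFolds = config$nFolds, foldSeed = config$foldSeed,
                  lookupMethod = config$lookupMethod)
}

#' Fit a choice-conditioned tuning-field model
#'
#' Runs the field-estimation pipeline separately on leftward-choice and
#' rightward-choice trials, giving two sub-models with independently
#' cross-validated bandwidths. With \code{includeTheta = TRUE} each
#' sub-model is a 2-D field over (z, theta) — the f(z, theta, d) model; with
#' \code{FALSE} each is a position profile flat in theta — the f(z, d)
#' model, using the same regularized-ratio formula collapsed to 1-D.
#'
#' @param session a \code{\link{NavSession}}.
#' @param trace response vector aligned with the session frames.
#' @param grid a \code{\link{gridSpec}}.
#' @param config an \code{\link{estimatorConfig}}.
#' @param includeTheta logical: keep the heading axis?
#' @return A \code{\link{DecisionConditionedEstimate}}.
#' @export
fitDecisionModel <- function(session, trace, grid, config = estimatorConfig(),
                             includeTheta = TRUE) {
  tr <- trials(session)
  for (cl in c("L", "R"))
    if (sum(tr$choice == cl) < config$nFolds)
      stop("choice class '", cl, "' has fewer trials than folds")
  if (!includeTheta) {
    grid <- marginalGrid(grid)
    config <- marginalConfig(config)
  }
  sub <- lapply(c("L", "R"), function(cl)
    selectBandwidths(session, trace, grid, config,
                     trialSubset = tr$trialId[tr$choice == cl])$field)
  new("DecisionConditionedEstimate", left = sub[[1]], right = sub[[2]],
      includeTheta = includeTheta)
}

#' Predict a trace from a fitted model
#'
#' Looks up f(z, theta), f(z | d) or f(z, theta | d) along the trajectory of
#' the requested trials, using each trial's actual decision for
#' choice-conditioned models. Requesting a trial that was inside the model's
#' training set violates the cross-validation contract and raises an error.
#'
#' @param model a \code{\link{FieldEstimate}} or
#'   \code{\link{DecisionConditionedEstimate}}.
#' @param session a \code{\link{NavSession}}.
#' @param trialSubset trial ids to predict (default: all trials).
#' @param method field lookup method.
#' @return numeric vector of predictions, one per frame of the requested
#'   trials (in session frame order), with the frame indices in attribute
#'   \code{"frames"}.
#' @export
predictTrace <- function(model, session, trialSubset = NULL,
                         method = "bilinear") {
  tr <- trials(session)
  if (is.null(trialSubset)) trialSubset <- tr$trialId
  traj <- trajectory(session)
  frames <- which(traj$trialId %in% trialSubset)
  checkContract <- function(fe, ids) {
    bad <- intersect(ids, fe@trainedTrials)
    if (length(bad))
      stop("cross-validation contract violation: trial(s) ",
           paste(utils::head(bad, 3), collapse = ", "),
           " are inside the model's training set")
  }
  if (is(model, "FieldEstimate")) {
    checkContract(model, trialSubset)
    pred <- fieldLookup(model, traj$z[frames], traj$theta[frames],
                        method = method)
  } else if (is(model, "DecisionConditionedEstimate")) {
    ch <- frameChoice(session)[frames]
    trChoice <- tr$choice[match(trialSubset, tr$trialId)]
    checkContract(model@left, trialSubset[trChoice == "L"])
    checkContract(model@right, trialSubset[trChoice == "R"])
    pred <- numeric(length(frames))
    for (cl in c("L", "R")) {
      sub <- if (cl == "L") model@left else model@right
      i <- which(ch == cl)
      if (length(i))
        pred[i] <- fieldLookup(sub, traj$z[frames[i]], traj$theta[frames[i]],
                               method = method)
    }
  } else stop("unsupported model class: ", class(model)[1])
  attr(pred, "frames") <- frames
  pred
}

## Rank-sum (Mann-Whitney) auROC: probability that a random draw from `pos`
## exceeds a random draw from `neg`, ties counted half. Midranks make this
## exactly the normalized U statistic.
rankSumAuroc <- function(neg, pos) {
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Heading/choice confound exclusion mask
#'
#' For each position bin, computes the auROC between the heading samples of
#' left-choice and right-choice frames falling in that bin — a measure of
#' how well choice can be predicted from heading at that position. The
#' auROC is rectified to \code{max(A, 1 - A)} so the threshold is
#' side-agnostic. Bins where it exceeds the threshold (where decision and
#' heading are nearly indistinguishable as predictors) are excluded from the
#' quality-of-fit analysis; bins visited by only one choice class are
#' excluded by convention. The mask is computed once per session from
#' behavior only.
#'
#' @param session a \code{\link{NavSession}}.
#' @param zEdges position bin edges (cm).
#' @param threshold auROC exclusion threshold (default 0.95, strict
#'   inequality).
#' @return data.frame of class \code{"ExclusionMask"} with columns zLo, zHi,
#'   auroc, excluded.
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 40, seed = 1))
#' mask <- aurocExclusion(sess, defaultGrid()@zEdges)
#' sum(mask$excluded)
#' @export
aurocExclusion <- function(session, zEdges, threshold = 0.95) {
  traj <- trajectory(session)
  ch <- frameChoice(session)
  stopIfNot(all(c("L", "R") %in% ch), "both choices must be present")
  iz <- axisBin(traj$z, zEdges, "z")
  nb <- length(zEdges) - 1L
  auroc <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    inBin <- iz == b
    thL <- traj$theta[inBin & ch == "L"]
    thR <- traj$theta[inBin & ch == "R"]
    if (length(thL) && length(thR)) {
      a <- rankSumAuroc(thL, thR)
      auroc[b] <- max(a, 1 - a)
    }
  }
  out <- data.frame(zLo = zEdges[-length(zEdges)], zHi = zEdges[-1],
                    auroc = auroc,
                    excluded = is.na(auroc) | auroc > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "zEdges") <- zEdges
  class(out) <- c("ExclusionMask", "data.frame")
  out
}

#' Trial-averaged correlation between data and prediction
#'
#' Drops frames falling in excluded position bins, averages the remaining
#' frames within each trial (one actual and one predicted value per trial),
#' and returns the Pearson correlation across trials. Returns NA (reported
#' as missing, never as 0) if either trial-mean vector has zero variance.
#'
#' @param actual,predicted full-session response vectors (frames).
#' @param session a \code{\link{NavSession}}.
#' @param mask an \code{\link{aurocExclusion}} mask (NULL: keep all frames).
#' @param minTrials minimum number of trials that must survive masking.
#' @return Pearson correlation across trials (possibly NA).
#' @export
fitQuality <- function(actual, predicted, session, mask = NULL,
                       minTrials = 3) {
  traj <- trajectory(session)
  stopIfNot(length(actual) == nrow(traj) && length(predicted) == nrow(traj),
            "actual and predicted must be aligned with session frames")
  keep <- rep(TRUE, nrow(traj))
  if (!is.null(mask)) {
    zEdges <- attr(mask, "zEdges")
    iz <- axisBin(traj$z, zEdges, "z")
    keep <- !mask$excluded[iz]
  }
  keep <- keep & !is.na(predicted)
  if (!any(keep)) stop("no frames survive the exclusion mask")
  aM <- tapply(actual[keep], traj$trialId[keep], mean)
  pM <- tapply(predicted[keep], traj$trialId[keep], mean)
  if (length(aM) < minTrials)
    stop("fewer than ", minTrials, " trials survive the exclusion mask")
  if (stats::sd(aM) == 0 || stats::sd(pM) == 0) return(NA_real_)
  stats::cor(aM, pM)
}

#' Cross-validated comparison of the three response models
#'
#' For every neuron, selects bandwidths for the position-heading model
#' f(z, theta), the position-decision model f(z, d) and the extended model
#' f(z, theta, d) (the two decision models per choice class), then produces
#' 10-fold cross-validated predictions: for each choice-balanced group of
#' trials, activity is predicted from fields re-estimated on the other 90%
#' of trials at the selected bandwidths. Each model is scored by the
#' trial-averaged Pearson correlation under the session's auROC exclusion
#' mask, and per-neuron differences plus median / m.a.d. summaries are
#' reported.
#'
#' @param session a \code{\link{NavSession}} with a response assay.
#' @param grid a \code{\link{gridSpec}}.
#' @param config an \code{\link{estimatorConfig}}.
#' @param aurocThreshold exclusion threshold.
#' @param returnPredictions if TRUE, keep the cross-validated predicted
#'   traces (neurons x frames, per model) for sequence reconstruction.
#' @return list of class \code{"FitQualityReport"}: \code{perNeuron}
#'   (data.frame of correlations rZT, rZD, rZTD and their differences),
#'   \code{summary} (median and m.a.d. of each column), \code{mask},
#'   \code{nUndefined}, and optionally \code{predictions}.
#' @export
compareModels <- function(session, grid = defaultGrid(geometry(session)),
                          config = estimatorConfig(), aurocThreshold = 0.95,
                          returnPredictions = FALSE) {
  R <- responses(session)
  stopIfNot(nrow(R) >= 1, "session must contain at least one neuron")
  tr <- trials(session)
  traj <- trajectory(session)
  mask <- aurocExclusion(session, grid@zEdges, aurocThreshold)
  fold <- makeFolds(tr$choice, config$nFolds, config$foldSeed)
  nFrames <- nrow(traj)
  g1 <- marginalGrid(grid)
  cfg1 <- marginalConfig(config)

  predZT <- matrix(NA_real_, nrow(R), nFrames, dimnames = dimnames(R))
  predZD <- predZT
  predZTD <- predZT

  for (i in seq_len(nrow(R))) {
    trace <- R[i, ]
    bwZT <- selectBandwidths(session, trace, grid, config)$bandwidths
    bwCl <- lapply(c(L = "L", R = "R"), function(cl) {
      ids <- tr$trialId[tr$choice == cl]
      if (length(ids) < config$nFolds)
        stop("choice class '", cl, "' has fewer trials than folds")
      list(zd = selectBandwidths(session, trace, g1, cfg1,
                                 trialSubset = ids)$bandwidths,
           ztd = selectBandwidths(session, trace, grid, config,
                                  trialSubset = ids)$bandwidths)
    })
    for (f in seq_len(config$nFolds)) {
      testIds <- tr$trialId[fold == f]
      trainIds <- tr$trialId[fold != f]
      testFrames <- which(traj$trialId %in% testIds)
      ## f(z, theta)
      mTrain <- traj$trialId %in% trainIds
      maps <- binTrajectory(session, trace, grid, frameMask = mTrain)
      fm <- sum(maps@signal) / sum(maps@occupancy)
      fld <- estimateField(maps, bwZT, config$lambda, fm,
                           trainedTrials = trainIds)
      p <- predictTrace(fld, session, testIds, method = config$lookupMethod)
      predZT[i, attr(p, "frames")] <- p
      ## decision-conditioned models
      for (cl in c("L", "R")) {
        clTrain <- tr$trialId[tr$choice == cl & fold != f]
        clTestFrames <- testFrames[frameChoice(session)[testFrames] == cl]
        if (!length(clTestFrames)) next
        mcl <- traj$trialId %in% clTrain
        for (variant in c("zd", "ztd")) {
          gU <- if (variant == "zd") g1 else grid
          mapsC <- binTrajectory(session, trace, gU, frameMask = mcl)
          fmC <- sum(mapsC@signal) / sum(mapsC@occupancy)
          fldC <- estimateField(mapsC, bwCl[[cl]][[variant]], config$lambda,
                                fmC, trainedTrials = clTrain)
          pv <- fieldLookup(fldC, traj$z[clTestFrames],
                            traj$theta[clTestFrames],
                            method = config$lookupMethod)
          if (variant == "zd") predZD[i, clTestFrames] <- pv
          else predZTD[i, clTestFrames] <- pv
        }
      }
    }
  }

  rOne <- function(pred, i) fitQuality(R[i, ], pred[i, ], session, mask)
  per <- data.frame(
    neuron = rownames(R),
    rZT = vapply(seq_len(nrow(R)), function(i) rOne(predZT, i), numeric(1)),
    rZD = vapply(seq_len(nrow(R)), function(i) rOne(predZD, i), numeric(1)),
    rZTD = vapply(seq_len(nrow(R)), function(i) rOne(predZTD, i), numeric(1)))
  per$dZTvsZD <- per$rZT - per$rZD
  per$dZTDvsZT <- per$rZTD - per$rZT
  per$dZTDvsZD <- per$rZTD - per$rZD
  num <- per[, -1]
  summary <- data.frame(
    statistic = names(num),
    median = vapply(num, function(x) stats::median(x, na.rm = TRUE), numeric(1)),
    mad = vapply(num, madAboutMedian, numeric(1)),
    row.names = NULL)
  out <- list(perNeuron = per, summary = summary, mask = mask,
              nUndefined = sum(!stats::complete.cases(num)))
  if (returnPredictions)
    out$predictions <- list(zt = predZT, zd = predZD, ztd = predZTD)
  class(out) <- "FitQualityReport"
  out
}

#' @export
print.FitQualityReport <- function(x, ...) {
  cat("FitQualityReport:", nrow(x$perNeuron), "neurons,",
      x$nUndefined, "with undefined correlation\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Choice-conditioned activation sequences
#'
#' For each neuron, trial-averages its activity separately over left-choice
#' and right-choice trials on a normalized-time axis (0-1, fixed number of
#' bins; per-trial activity is linearly interpolated to the bin centers).
#' Neurons are assigned to the choice class with the larger peak average,
#' ordered within class by peak time, and each row is peak-normalized. An
#' ordering derived from one data set (e.g. measured activity) can be reused
#' for another (e.g. model predictions) to compare sequence structure.
#'
#' @param session a \code{\link{NavSession}}.
#' @param mat neurons x frames activity matrix (measured or predicted).
#' @param nBins number of normalized-time bins.
#' @param ordering optional \code{ordering} data.frame from a previous call;
#'   its class assignment and row order are then reused, and peak times are
#'   recomputed on the new data.
#' @return list of class \code{"ChoiceSequences"}: \code{left} and
#'   \code{right} peak-normalized matrices (ordered neurons x time bins) and
#'   \code{ordering} (neuron, class, peakBin).
#' @export
buildChoiceSequences <- function(session, mat, nBins = 50, ordering = NULL) {
  stopIfNot(is.matrix(mat) && ncol(mat) == ncol(session),
            "mat must be neurons x frames, aligned with the session")
  mat[is.na(mat)] <- 0
  traj <- trajectory(session)
  tr <- trials(session)
  centers <- (seq_len(nBins) - 0.5) / nBins
  nN <- nrow(mat)
  sums <- list(L = matrix(0, nN, nBins), R = matrix(0, nN, nBins))
  cnt <- c(L = 0, R = 0)
  for (k in seq_len(nrow(tr))) {
    idx <- which(traj$trialId == tr$trialId[k])
    tt <- traj$t[idx]
    nt <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
    i <- findInterval(centers, nt)
    i <- pmin(pmax(i, 1L), length(idx) - 1L)
    w <- (centers - nt[i]) / (nt[i + 1] - nt[i])
    w <- pmin(pmax(w, 0), 1)
    sub <- mat[, idx, drop = FALSE]
    interp <- sub[, i, drop = FALSE] * rep(1 - w, each = nN) +
      sub[, i + 1, drop = FALSE] * rep(w, each = nN)
    cl <- tr$choice[k]
    sums[[cl]] <- sums[[cl]] + interp
    cnt[cl] <- cnt[cl] + 1
  }
  avg <- list(L = sums$L / max(cnt["L"], 1), R = sums$R / max(cnt["R"], 1))
  if (is.null(ordering)) {
    maxL <- apply(avg$L, 1, max)
    maxR <- apply(avg$R, 1, max)
    class <- ifelse(maxR > maxL, "R", "L")
  } else class <- ordering$class
  peakBin <- vapply(seq_len(nN), function(i)
    which.max(avg[[class[i]]][i, ]), integer(1))
  ord <- data.frame(neuron = seq_len(nN), class = class, peakBin = peakBin)
  if (!is.null(ordering)) {
    rowOrder <- ordering$neuron
  } else {
    rowOrder <- order(class, peakBin)
    ord <- ord[rowOrder, ]
    rowOrder <- ord$neuron
  }
  normRow <- function(x) if (max(x) > 0) x / max(x) else x
  pick <- function(cl) {
    sel <- rowOrder[class[rowOrder] == cl]
    m <- avg[[cl]][sel, , drop = FALSE]
    if (nrow(m))
      m <- matrix(t(apply(m, 1, normRow)), nrow = nrow(m),
                  dimnames = list(rownames(mat)[sel] %||% as.character(sel),
                                  NULL))
    m
  }
  structure(list(left = pick("L"), right = pick("R"),
                 ordering = if (is.null(ordering)) ord
                            else ord[match(rowOrder, ord$neuron), ],
                 nBins = nBins),
            class = "ChoiceSequences")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
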