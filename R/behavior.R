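## Psychometric curves, heading-based choice predictability along the
## corridor, and heading-conditional psychometric functions. The
## cross-validated threshold classifier defined here is shared verbatim with
## the decoder's neurometric analysis.

## Heading of each trial at its first crossing of position zStar.
## thetaSource is a per-frame heading vector (true theta by default; decoded
## theta-hat for the neurometric analysis). Returns one row per trial that
## reaches zStar.
thetaAtCrossing <- function(session, zStar, thetaSource = NULL) {
  traj <- trajectory(session)
  if (is.null(thetaSource)) thetaSource <- traj$theta
  stopIfNot(length(thetaSource) == nrow(traj),
            "thetaSource must be aligned with session frames")
  tr <- trials(session)
  rows <- lapply(seq_len(nrow(tr)), function(k) {
    idx <- which(traj$trialId == tr$trialId[k])
    hit <- idx[traj$z[idx] >= zStar][1]
    if (is.na(hit)) return(NULL)
    data.frame(trialId = tr$trialId[k], theta = thetaSource[hit],
               choice = tr$choice[k], contrast = tr$contrast[k],
               isRepeat = tr$isRepeat[k])
  })
  do.call(rbind, rows)
}

#' Cross-validated single-threshold choice classifier
#'
#' Predicts the trial's final choice from a scalar (the heading at a
#' checkpoint, measured or decoded). On each training fold the threshold
#' and its orientation (rightward above or below it) are chosen to maximize
#' training accuracy; predictability is the mean accuracy on the held-out
#' folds. This is the weakest decision rule consistent with predicting a
#' binary choice from one scalar, and the identical code path serves both
#' the behavioral and the neurometric analyses.
#'
#' @param x numeric predictor, one value per trial.
#' @param choice "L"/"R" per trial.
#' @param nFolds number of choice-balanced folds.
#' @param seed fold-assignment seed.
#' @return list: \code{accuracy} (mean test accuracy), \code{se} (SEM across
#'   folds), \code{foldAccuracy}, and \code{predicted} (cross-validated
#'   predicted choice per trial).
#' @export
choicePredictability <- function(x, choice, nFolds = 10, seed = 1) {
  stopIfNot(length(x) == length(choice), "x and choice must be parallel")
  ok <- is.finite(x)
  x <- x[ok]; choice <- choice[ok]
  stopIfNot(all(c("L", "R") %in% choice), "both choices must be present")
  fold <- makeFolds(choice, nFolds, seed)
  yR <- choice == "R"
  predicted <- rep(NA_character_, length(x))
  foldAcc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    test <- fold == f
    xt <- x[!test]; yt <- yR[!test]
    xs <- sort(unique(xt))
    thr <- c(xs[1] - 1, (xs[-1] + xs[-length(xs)]) / 2, xs[length(xs)] + 1)
    accAbove <- vapply(thr, function(h) mean((xt > h) == yt), numeric(1))
    accBelow <- vapply(thr, function(h) mean((xt < h) == yt), numeric(1))
    if (max(accAbove) >= max(accBelow)) {
      h <- thr[which.max(accAbove)]
      predTest <- ifelse(x[test] > h, "R", "L")
    } else {
      h <- thr[which.max(accBelow)]
      predTest <- ifelse(x[test] < h, "R", "L")
    }
    predicted[test] <- predTest
    foldAcc[f] <- mean(predTest == choice[test])
  }
  out <- rep(NA_character_, length(ok))
  out[ok] <- predicted
  list(accuracy = mean(foldAcc),
       se = stats::sd(foldAcc) / sqrt(nFolds),
       foldAccuracy = foldAcc, predicted = out)
}

#' Psychometric curve of a session
#'
#' Empirical fraction of rightward choices per signed contrast with
#' Clopper-Pearson 95% confidence intervals, and a maximum-likelihood fit of
#' the lapse-equipped cumulative-Gaussian
#' \code{P(R | c) = lapse + (1 - 2 lapse) * Phi(slope * (c - bias))}
#' (the standard 2AFC form, and the simulator's generating model). Baited
#' repeat trials are excluded by default because they bias
#' contrast-conditional choice frequencies.
#'
#' @param trials a trials data.frame (from \code{\link{trials}}) or a
#'   \code{\link{NavSession}}.
#' @param excludeRepeats drop baited repeats before fitting?
#' @param fit fit the sigmoid (skipped automatically with a single contrast
#'   level)?
#' @return list of class \code{"PsychometricData"}: \code{points}
#'   (contrast, nTrials, nRight, fracRight, ciLo, ciHi) and \code{fit}
#'   (bias, slope, lapse, their SEs and Wald 95% CIs, logLik), or
#'   \code{fit = NULL} when skipped.
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 100, seed = 1))
#' psychometric(sess)$points
#' @export
psychometric <- function(trials, excludeRepeats = TRUE, fit = TRUE) {
  if (is(trials, "NavSession")) trials <- as.data.frame(trials@trials)
  tr <- trials
  if (excludeRepeats) tr <- tr[!tr$isRepeat, ]
  stopIfNot(nrow(tr) >= 1, "no trials left after filtering")
  lev <- sort(unique(tr$contrast))
  n <- vapply(lev, function(cc) sum(tr$contrast == cc), numeric(1))
  k <- vapply(lev, function(cc) sum(tr$contrast == cc & tr$choice == "R"),
              numeric(1))
  points <- data.frame(
    contrast = lev, nTrials = n, nRight = k, fracRight = k / n,
    ciLo = ifelse(k == 0, 0, stats::qbeta(0.025, k, n - k + 1)),
    ciHi = ifelse(k == n, 1, stats::qbeta(0.975, k + 1, n - k)))
  fitRes <- NULL
  if (fit && length(lev) >= 2) {
    negLL <- function(p) {
      pr <- psychometricProb(lev, p[2], p[1], p[3])
      pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
      -sum(k * log(pr) + (n - k) * log(1 - pr))
    }
    starts <- list(c(0, 2, 0.02), c(0, 8, 0.05), c(0, 25, 0.1))
    best <- NULL
    for (s in starts) {
      o <- try(stats::optim(s, negLL, method = "L-BFGS-B",
                            lower = c(-2, 0.01, 1e-4),
                            upper = c(2, 200, 0.49), hessian = TRUE),
               silent = TRUE)
      if (!inherits(o, "try-error") &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (!is.null(best)) {
      se <- rep(NA_real_, 3)
      vc <- try(solve(best$hessian), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0))
        se <- sqrt(diag(vc))
      fitRes <- list(bias = best$par[1], slope = best$par[2],
                     lapse = best$par[3],
                     se = c(bias = se[1], slope = se[2], lapse = se[3]),
                     ci = data.frame(
                       parameter = c("bias", "slope", "lapse"),
                       lo = best$par - 1.96 * se,
                       hi = best$par + 1.96 * se),
                     logLik = -best$value)
    }
  }
  structure(list(points = points, fit = fitRes, nTrials = nrow(tr)),
            class = "PsychometricData")
}

#' @export
print.PsychometricData <- function(x, ...) {
  cat("PsychometricData:", x$nTrials, "trials,",
      nrow(x$points), "contrast levels\n")
  print(x$points, digits = 3)
  if (!is.null(x$fit))
    cat(sprintf("fit: bias = %.3f, slope = %.2f, lapse = %.3f\n",
                x$fit$bias, x$fit$slope, x$fit$lapse))
  invisible(x)
}

#' Choice predictability from heading along the corridor
#'
#' At each position checkpoint z*, takes each trial's heading at its first
#' crossing of z* and scores how well the final choice can be predicted from
#' it with the cross-validated threshold classifier
#' (\code{\link{choicePredictability}}). Predictability rises toward the end
#' of the corridor as trajectories toward the two choices diverge.
#'
#' @param session a \code{\link{NavSession}}.
#' @param zCheckpoints positions (cm) at which to evaluate.
#' @param nFolds,seed classifier cross-validation settings.
#' @param thetaSource optional per-frame heading substitute (e.g. decoded
#'   heading for the neurometric analysis); default: the actual heading.
#' @return list of class \code{"PredictabilityCurve"}: \code{curve}
#'   (z, predictability, se, nTrials, nSkipped) and \code{predicted}
#'   (per-checkpoint data.frames of cross-validated predicted choices).
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 60, seed = 1))
#' headingChoicePredictability(sess, c(30, 60, 90))$curve
#' @export
headingChoicePredictability <- function(session, zCheckpoints,
                                        nFolds = 10, seed = 1,
                                        thetaSource = NULL) {
  stopIfNot(all(c("L", "R") %in% trials(session)$choice),
            "both choices must be present")
  rows <- list(); preds <- list()
  for (zStar in zCheckpoints) {
    cross <- thetaAtCrossing(session, zStar, thetaSource)
    nSkip <- nTrials(session) - NROW(cross)
    if (is.null(cross) || length(unique(cross$choice)) < 2 ||
        nrow(cross) < nFolds) {
      rows[[length(rows) + 1]] <- data.frame(
        z = zStar, predictability = NA_real_, se = NA_real_,
        nTrials = NROW(cross), nSkipped = nSkip)
      next
    }
    cp <- choicePredictability(cross$theta, cross$choice, nFolds, seed)
    rows[[length(rows) + 1]] <- data.frame(
      z = zStar, predictability = cp$accuracy, se = cp$se,
      nTrials = nrow(cross), nSkipped = nSkip)
    preds[[as.character(zStar)]] <-
      data.frame(trialId = cross$trialId, contrast = cross$contrast,
                 isRepeat = cross$isRepeat, choice = cross$choice,
                 predicted = cp$predicted)
  }
  structure(list(curve = do.call(rbind, rows), predicted = preds),
            class = "PredictabilityCurve")
}

#' @export
print.PredictabilityCurve <- function(x, ...) {
  cat("PredictabilityCurve:\n")
  print(x$curve, digits = 3)
  invisible(x)
}

#' Heading-conditional psychometric curves
#'
#' At each checkpoint, replaces the actual choice with the
#' threshold-classifier's cross-validated prediction from heading and
#' recomputes the psychometric points. As the animal progresses through the
#' corridor these predicted-choice curves converge to the actual
#' psychometric curve.
#'
#' @inheritParams headingChoicePredictability
#' @param excludeRepeats drop baited repeats from the fraction computation
#'   (matching \code{\link{psychometric}}).
#' @return list of class \code{"ConditionalPsychometric"}: \code{actual}
#'   (the psychometric points), \code{byCheckpoint} (per-checkpoint
#'   predicted-choice points), and \code{meanAbsDiff} per checkpoint.
#' @export
conditionalPsychometric <- function(session, zCheckpoints, nFolds = 10,
                                    seed = 1, thetaSource = NULL,
                                    excludeRepeats = TRUE) {
  act <- psychometric(session, excludeRepeats = excludeRepeats, fit = FALSE)
  hp <- headingChoicePredictability(session, zCheckpoints, nFolds, seed,
                                    thetaSource)
  by <- list(); mad <- numeric(0)
  for (zc in names(hp$predicted)) {
    p <- hp$predicted[[zc]]
    if (excludeRepeats) p <- p[!p$isRepeat, ]
    p <- p[!is.na(p$predicted), ]
    lev <- sort(unique(p$contrast))
    pts <- data.frame(
      contrast = lev,
      nTrials = vapply(lev, function(cc) sum(p$contrast == cc), numeric(1)),
      fracRightPredicted = vapply(lev, function(cc)
        mean(p$predicted[p$contrast == cc] == "R"), numeric(1)))
    by[[zc]] <- pts
    common <- intersect(lev, act$points$contrast)
    mad[zc] <- mean(abs(
      pts$fracRightPredicted[match(common, pts$contrast)] -
        act$points$fracRight[match(common, act$points$contrast)]))
  }
  structure(list(actual = act$points, byCheckpoint = by, meanAbsDiff = mad),
            class = "ConditionalPsychometric")
}
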