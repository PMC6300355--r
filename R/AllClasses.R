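#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## ---------------------------------------------------------------------------
## MazeGeometry
## ---------------------------------------------------------------------------

#' Geometry of the virtual T-maze corridor
#'
#' Describes the corridor the animal navigates: its length along the position
#' axis z and the allowed range of the heading angle theta. The defaults match
#' a 110 cm corridor with heading bounded in [-90, +90] degrees.
#'
#' @slot corridorLength corridor length in cm.
#' @slot headingMin,headingMax heading bounds in degrees.
#' @slot zMin start position in cm.
#' @export
setClass("MazeGeometry",
  representation(corridorLength = "numeric", headingMin = "numeric",
                 headingMax = "numeric", zMin = "numeric"),
  prototype(corridorLength = 110, headingMin = -90, headingMax = 90, zMin = 0))

setValidity("MazeGeometry", function(object) {
  msg <- NULL
  if (length(object@corridorLength) != 1 || object@corridorLength <= 0)
    msg <- c(msg, "corridorLength must be a single positive number")
  if (!(object@headingMin < 0 && 0 < object@headingMax))
    msg <- c(msg, "heading bounds must satisfy headingMin < 0 < headingMax")
  if (object@zMin < 0 || object@zMin >= object@corridorLength)
    msg <- c(msg, "zMin must lie in [0, corridorLength)")
  if (is.null(msg)) TRUE else msg
})

#' @param corridorLength,headingMin,headingMax,zMin see slots.
#' @return A \code{MazeGeometry} object.
#' @rdname MazeGeometry-class
#' @examples
#' mazeGeometry()
#' @export
mazeGeometry <- function(corridorLength = 110, headingMin = -90,
                         headingMax = 90, zMin = 0) {
  new("MazeGeometry", corridorLength = corridorLength, headingMin = headingMin,
      headingMax = headingMax, zMin = zMin)
}

setMethod("show", "MazeGeometry", function(object) {
  cat("MazeGeometry: corridor ", object@zMin, "-", object@corridorLength,
      " cm, heading [", object@headingMin, ", ", object@headingMax,
      "] deg\n", sep = "")
})

#' Accessors for MazeGeometry
#' @param x a \code{MazeGeometry}.
#' @return a numeric scalar.
#' @export
corridorLength <- function(x) x@corridorLength
#' @rdname corridorLength
#' @export
headingBounds <- function(x) c(x@headingMin, x@headingMax)

## ---------------------------------------------------------------------------
## GridSpec
## ---------------------------------------------------------------------------

#' Binning grid over position-heading space
#'
#' Bin edges along z (cm) and theta (deg) used for occupancy/signal maps,
#' tuning-field estimation and decoding. Edges must be strictly increasing
#' with at least two bins per axis.
#'
#' @slot zEdges,thetaEdges strictly increasing numeric bin edges.
#' @export
setClass("GridSpec",
  representation(zEdges = "numeric", thetaEdges = "numeric"))

setValidity("GridSpec", function(object) {
  msg <- NULL
  for (nm in c("zEdges", "thetaEdges")) {
    e <- slot(object, nm)
    if (length(e) < 3) msg <- c(msg, paste(nm, "must define at least 2 bins"))
    if (any(diff(e) <= 0)) msg <- c(msg, paste(nm, "must be strictly increasing"))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param zEdges,thetaEdges strictly increasing numeric bin edges.
#' @return A \code{GridSpec}.
#' @rdname GridSpec-class
#' @export
gridSpec <- function(zEdges, thetaEdges) {
  new("GridSpec", zEdges = as.numeric(zEdges), thetaEdges = as.numeric(thetaEdges))
}

#' Default analysis grid for a maze
#'
#' 2 cm x 3 deg bins spanning the maze; finer than plausible smoothing
#' bandwidths so that smoothing, not binning, controls the resolution of the
#' estimated fields.
#'
#' @param geometry a \code{MazeGeometry}.
#' @param zStep,thetaStep bin sizes in cm and deg.
#' @return A \code{GridSpec}.
#' @examples
#' defaultGrid(mazeGeometry())
#' @export
defaultGrid <- function(geometry = mazeGeometry(), zStep = 2, thetaStep = 3) {
  gridSpec(seq(geometry@zMin, geometry@corridorLength, by = zStep),
           seq(geometry@headingMin, geometry@headingMax, by = thetaStep))
}

#' Grid dimensions and bin centers
#' @param grid a \code{GridSpec}.
#' @return \code{gridDim}: integer vector (n z bins, n theta bins);
#'   \code{zCenters}/\code{thetaCenters}: numeric bin centers.
#' @export
gridDim <- function(grid) {
  c(length(grid@zEdges) - 1L, length(grid@thetaEdges) - 1L)
}
#' @rdname gridDim
#' @export
zCenters <- function(grid) {
  e <- grid@zEdges
  (e[-1] + e[-length(e)]) / 2
}
#' @rdname gridDim
#' @export
thetaCenters <- function(grid) {
  e <- grid@thetaEdges
  (e[-1] + e[-length(e)]) / 2
}

setMethod("show", "GridSpec", function(object) {
  d <- gridDim(object)
  cat("GridSpec: ", d[1], " z bins [", min(object@zEdges), ", ",
      max(object@zEdges), "] cm x ", d[2], " theta bins [",
      min(object@thetaEdges), ", ", max(object@thetaEdges), "] deg\n", sep = "")
})

## ---------------------------------------------------------------------------
## Bandwidths
## ---------------------------------------------------------------------------

#' Gaussian smoothing bandwidths
#'
#' Standard deviations of the Gaussian smoothing kernel along z (cm) and
#' theta (deg) used when filtering occupancy and signal maps.
#'
#' @slot sigmaZ,sigmaTheta positive numeric bandwidths (cm, deg).
#' @export
setClass("Bandwidths", representation(sigmaZ = "numeric", sigmaTheta = "numeric"))

setValidity("Bandwidths", function(object) {
  if (length(object@sigmaZ) != 1 || length(object@sigmaTheta) != 1 ||
      object@sigmaZ <= 0 || object@sigmaTheta <= 0)
    "sigmaZ and sigmaTheta must be single positive numbers"
  else TRUE
})

#' @param sigmaZ,sigmaTheta positive bandwidths in cm and deg.
#' @return A \code{Bandwidths} object.
#' @rdname Bandwidths-class
#' @export
bandwidths <- function(sigmaZ, sigmaTheta) {
  new("Bandwidths", sigmaZ = sigmaZ, sigmaTheta = sigmaTheta)
}

setMethod("show", "Bandwidths", function(object) {
  cat("Bandwidths: sigmaZ = ", object@sigmaZ, " cm, sigmaTheta = ",
      object@sigmaTheta, " deg\n", sep = "")
})

#' @rdname Bandwidths-class
#' @param x a \code{Bandwidths}.
#' @export
sigmaZ <- function(x) x@sigmaZ
#' @rdname Bandwidths-class
#' @export
sigmaTheta <- function(x) x@sigmaTheta

## ---------------------------------------------------------------------------
## BinnedMaps
## ---------------------------------------------------------------------------

#' Occupancy and accumulated-signal maps
#'
#' Per-bin visit counts (occupancy, M_occ) and summed responses (signal,
#' M_sig) over a \code{GridSpec}, accumulated from a trajectory and an
#' aligned fluorescence trace. Matrices are z (rows) by theta (columns).
#'
#' @slot occupancy,signal numeric matrices, z bins x theta bins.
#' @slot grid the \code{GridSpec} the maps live on.
#' @export
setClass("BinnedMaps",
  representation(occupancy = "matrix", signal = "matrix", grid = "GridSpec"))

setValidity("BinnedMaps", function(object) {
  d <- gridDim(object@grid)
  msg <- NULL
  if (!all(dim(object@occupancy) == d) || !all(dim(object@signal) == d))
    msg <- c(msg, "map dimensions must match the grid")
  if (any(object@occupancy < 0)) msg <- c(msg, "occupancy must be non-negative")
  if (any(object@signal[object@occupancy == 0] != 0))
    msg <- c(msg, "signal must be zero wherever occupancy is zero")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "BinnedMaps", function(object) {
  cat("BinnedMaps on ", paste(gridDim(object@grid), collapse = " x "),
      " grid; total occupancy ", sum(object@occupancy), "\n", sep = "")
})

#' @rdname BinnedMaps-class
#' @param x a \code{BinnedMaps}.
#' @export
occupancy <- function(x) x@occupancy
#' @rdname BinnedMaps-class
#' @export
signalMap <- function(x) x@signal

## ---------------------------------------------------------------------------
## FieldEstimate
## ---------------------------------------------------------------------------

#' Estimated position-heading tuning field
#'
#' The regularized smoothed-ratio estimate of a neuron's expected response as
#' a function of (z, theta):
#' F(z, theta) = (M_sig_filt + lambda * F_mean) / (M_occ_filt + lambda),
#' where both maps are filtered with the same Gaussian kernel. Doubles as the
#' mean response mu_i(z, theta) of the decoder's Gaussian response model.
#'
#' @slot values matrix of per-bin expected responses (z x theta).
#' @slot grid the \code{GridSpec}.
#' @slot bandwidths the smoothing \code{Bandwidths} used.
#' @slot lambda occupancy-count regularizer.
#' @slot fMean the neuron's mean response used in the regularizer.
#' @slot cvError cross-validated normalized error at the selected bandwidths
#'   (NA when not produced by cross-validation).
#' @slot trainedTrials integer ids of the trials the field was estimated from
#'   (empty means all; used to enforce the cross-validation contract).
#' @export
setClass("FieldEstimate",
  representation(values = "matrix", grid = "GridSpec",
                 bandwidths = "Bandwidths", lambda = "numeric",
                 fMean = "numeric", cvError = "numeric",
                 trainedTrials = "integer"),
  prototype(cvError = NA_real_, trainedTrials = integer(0)))

setValidity("FieldEstimate", function(object) {
  msg <- NULL
  if (!all(dim(object@values) == gridDim(object@grid)))
    msg <- c(msg, "values dimensions must match the grid")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "field values must be finite everywhere")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FieldEstimate", function(object) {
  cat("FieldEstimate on ", paste(gridDim(object@grid), collapse = " x "),
      " grid; sigmaZ = ", object@bandwidths@sigmaZ, " cm, sigmaTheta = ",
      object@bandwidths@sigmaTheta, " deg, lambda = ", object@lambda,
      ", fMean = ", signif(object@fMean, 4),
      if (is.finite(object@cvError)) paste0(", cvError = ", signif(object@cvError, 4)),
      "\n", sep = "")
})

#' @rdname FieldEstimate-class
#' @param x a \code{FieldEstimate}.
#' @export
fieldValues <- function(x) x@values
#' @rdname FieldEstimate-class
#' @export
fieldBandwidths <- function(x) x@bandwidths
#' @rdname FieldEstimate-class
#' @export
cvError <- function(x) x@cvError

## ---------------------------------------------------------------------------
## DecisionConditionedEstimate
## ---------------------------------------------------------------------------

#' Choice-conditioned tuning-field model
#'
#' A pair of sub-models, one estimated from leftward-choice trials and one
#' from rightward-choice trials, each with its own cross-validation-selected
#' bandwidths. With \code{includeTheta = TRUE} this is the
#' position-heading-decision model f(z, theta, d); with \code{FALSE} it is
#' the position-decision model f(z, d), whose prediction is flat in theta
#' within each choice class.
#'
#' @slot left,right \code{FieldEstimate} sub-models on identical grids.
#' @slot includeTheta logical.
#' @export
setClass("DecisionConditionedEstimate",
  representation(left = "FieldEstimate", right = "FieldEstimate",
                 includeTheta = "logical"))

setValidity("DecisionConditionedEstimate", function(object) {
  gl <- object@left@grid; gr <- object@right@grid
  if (!identical(gl@zEdges, gr@zEdges) ||
      !identical(gl@thetaEdges, gr@thetaEdges))
    "left and right sub-models must share one grid"
  else TRUE
})

setMethod("show", "DecisionConditionedEstimate", function(object) {
  cat("DecisionConditionedEstimate (",
      if (object@includeTheta) "f(z, theta, d)" else "f(z, d)", ")\n",
      "  left : ", sep = "")
  show(object@left@bandwidths)
  cat("  right: ")
  show(object@right@bandwidths)
})

## ---------------------------------------------------------------------------
## NavSession
## ---------------------------------------------------------------------------

#' A virtual-navigation session with aligned population activity
#'
#' Extends \code{SummarizedExperiment}: the assay \code{"response"} holds one
#' row per neuron and one column per imaging frame; \code{colData} holds the
#' frame-aligned behavior (time \code{t}, \code{trialId}, position \code{z},
#' heading \code{theta}); per-trial metadata (contrast, choice, outcome,
#' baited-repeat flag) live in the \code{trials} slot.
#'
#' @slot trials a \code{DataFrame} with columns trialId, contrast, choice
#'   ("L"/"R"), correct, isRepeat.
#' @slot geometry the \code{MazeGeometry}.
#' @slot frameRate imaging frame rate in Hz.
#' @export
setClass("NavSession",
  contains = "SummarizedExperiment",
  representation(trials = "DataFrame", geometry = "MazeGeometry",
                 frameRate = "numeric"))

setValidity("NavSession", function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("t", "trialId", "z", "theta")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  tr <- object@trials
  needT <- c("trialId", "contrast", "choice", "correct", "isRepeat")
  if (!all(needT %in% colnames(tr)))
    return(paste("trials must contain", paste(needT, collapse = ", ")))
  if (!all(cd$trialId %in% tr$trialId))
    msg <- c(msg, "every sample's trialId must exist in trials")
  cnt <- table(cd$trialId)
  if (any(cnt < 2)) msg <- c(msg, "every trial must have at least 2 samples")
  g <- object@geometry
  if (any(cd$z < 0 - 1e-9) || any(cd$z > g@corridorLength + 1e-9))
    msg <- c(msg, "z outside [0, corridorLength]")
  if (any(cd$theta < g@headingMin - 1e-9) || any(cd$theta > g@headingMax + 1e-9))
    msg <- c(msg, "theta outside heading bounds")
  if (any(!object@trials$choice %in% c("L", "R")))
    msg <- c(msg, "choice must be 'L' or 'R'")
  dt <- unlist(tapply(cd$t, cd$trialId, function(x) diff(x)), use.names = FALSE)
  if (length(dt) && any(dt <= 0))
    msg <- c(msg, "t must be strictly increasing within each trial")
  if (is.null(msg)) TRUE else msg
})

#' Construct a NavSession
#'
#' @param trials data.frame with columns trialId, contrast, choice, correct,
#'   isRepeat.
#' @param samples data.frame with columns t, trialId, z, theta (one row per
#'   imaging frame).
#' @param responses optional numeric matrix, neurons x frames.
#' @param geometry a \code{MazeGeometry}.
#' @param frameRate frame rate in Hz.
#' @param population optional data.frame of ground-truth neuron parameters
#'   (stored in \code{metadata} for parameter-recovery analyses).
#' @return A \code{NavSession}.
#' @export
navSession <- function(trials, samples, responses = NULL,
                       geometry = mazeGeometry(), frameRate = 7.5,
                       population = NULL) {
  nFrames <- nrow(samples)
  if (is.null(responses))
    responses <- matrix(numeric(0), nrow = 0, ncol = nFrames)
  responses <- as.matrix(responses)
  stopIfNot(ncol(responses) == nFrames,
            "responses must have one column per sample frame")
  if (nrow(responses) > 0 && is.null(rownames(responses)))
    rownames(responses) <- paste0("neuron_", seq_len(nrow(responses)))
  if (!all(is.finite(responses)))
    stop("responses must be finite")
  se <- SummarizedExperiment(
    assays = list(response = responses),
    colData = DataFrame(t = as.numeric(samples$t),
                        trialId = as.integer(samples$trialId),
                        z = as.numeric(samples$z),
                        theta = as.numeric(samples$theta)))
  obj <- new("NavSession", se,
             trials = DataFrame(trialId = as.integer(trials$trialId),
                                contrast = as.numeric(trials$contrast),
                                choice = as.character(trials$choice),
                                correct = as.logical(trials$correct),
                                isRepeat = as.logical(trials$isRepeat)),
             geometry = geometry, frameRate = frameRate)
  if (!is.null(population)) metadata(obj)$population <- population
  validObject(obj)
  obj
}

#' NavSession accessors
#'
#' \code{trials} returns the per-trial table; \code{trajectory} the per-frame
#' behavior (t, trialId, z, theta) as a data.frame; \code{responses} the
#' neurons x frames activity matrix; \code{geometry} and \code{frameRate} the
#' corresponding slots; \code{nTrials} and \code{nNeurons} the counts;
#' \code{frameChoice} the trial choice mapped onto frames.
#'
#' @param x a \code{NavSession}.
#' @name NavSession-accessors
NULL

#' @rdname NavSession-accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname NavSession-accessors
#' @export
setMethod("trials", "NavSession", function(x) as.data.frame(x@trials))

#' @rdname NavSession-accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname NavSession-accessors
#' @export
setMethod("trajectory", "NavSession",
          function(x) as.data.frame(colData(x))[, c("t", "trialId", "z", "theta")])

#' @rdname NavSession-accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @rdname NavSession-accessors
#' @export
setMethod("responses", "NavSession", function(x) assay(x, "response"))

#' @rdname NavSession-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname NavSession-accessors
#' @export
setMethod("geometry", "NavSession", function(x) x@geometry)

#' @rdname NavSession-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname NavSession-accessors
#' @export
setMethod("frameRate", "NavSession", function(x) x@frameRate)

#' @rdname NavSession-accessors
#' @export
nTrials <- function(x) nrow(x@trials)
#' @rdname NavSession-accessors
#' @export
nNeurons <- function(x) nrow(responses(x))

#' @rdname NavSession-accessors
#' @export
frameChoice <- function(x) {
  tr <- x@trials
  as.character(tr$choice)[match(colData(x)$trialId, tr$trialId)]
}

setMethod("show", "NavSession", function(object) {
  cat("NavSession: ", nTrials(object), " trials (",
      sum(!object@trials$isRepeat), " non-repeat), ", ncol(object),
      " frames at ", object@frameRate, " Hz, ", nNeurons(object),
      " neurons\n", sep = "")
  show(object@geometry)
})
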