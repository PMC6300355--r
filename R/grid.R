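## Binning of trajectories into occupancy/signal maps, mass-conserving
## Gaussian smoothing, and field lookup along a trajectory.

## Bin index along one axis with the half-open convention [lo, hi), final bin
## closed. Values outside the span are an error (never silently dropped).
axisBin <- function(x, edges, label) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  if (any(idx < 1L) || any(idx > length(edges) - 1L))
    stop("out-of-range ", label, " value(s): ",
         paste(utils::head(signif(x[idx < 1L | idx > length(edges) - 1L], 6), 3),
               collapse = ", "))
  idx
}

## (iz, itheta) bin indices for a set of frames.
frameBins <- function(grid, z, theta) {
  list(iz = axisBin(z, grid@zEdges, "z"),
       it = axisBin(theta, grid@thetaEdges, "theta"))
}

#' Bin a trajectory and trace into occupancy and signal maps
#'
#' Each selected frame adds 1 to its (z, theta) bin's occupancy and its
#' response value to the same bin's signal map. Frames on a bin edge follow
#' the half-open convention [lo, hi), except the final bin, which is closed.
#' Frames outside the grid span raise an error.
#'
#' @param session a \code{\link{NavSession}}.
#' @param trace numeric response vector aligned 1:1 with the session frames.
#' @param grid a \code{\link{gridSpec}}.
#' @param frameMask optional logical or integer index selecting frames (used
#'   for cross-validation folds). Default: all frames.
#' @return A \code{\link{BinnedMaps}} object.
#' @examples
#' sess <- simulateSession(simulationConfig(nTrials = 10, seed = 1))
#' maps <- binTrajectory(sess, rep(1, ncol(sess)), defaultGrid())
#' sum(occupancy(maps)) == ncol(sess)
#' @export
binTrajectory <- function(session, trace, grid, frameMask = NULL) {
  traj <- trajectory(session)
  stopIfNot(length(trace) == nrow(traj),
            "trace must be aligned 1:1 with session frames")
  sel <- seq_len(nrow(traj))
  if (!is.null(frameMask)) sel <- sel[frameMask]
  d <- gridDim(grid)
  occ <- matrix(0, d[1], d[2])
  sig <- matrix(0, d[1], d[2])
  if (length(sel)) {
    b <- frameBins(grid, traj$z[sel], traj$theta[sel])
    lin <- b$iz + (b$it - 1L) * d[1]
    occ[] <- tabulate(lin, d[1] * d[2])
    s <- rowsum(trace[sel], lin)
    sig[as.integer(rownames(s))] <- s
  }
  new("BinnedMaps", occupancy = occ, signal = sig, grid = grid)
}

## 1-D Gaussian smoothing matrix (n x n) with half-sample mirror boundary
## handling. The kernel is discretized at integer bin offsets, normalized to
## unit mass, and mass falling outside [1, n] is folded back by reflection;
## the resulting matrix is doubly stochastic, so smoothing conserves total
## mass exactly and leaves constant maps unchanged.
.kernelCache <- new.env(parent = emptyenv())

gaussKernelMatrix <- function(n, sigmaBins) {
  if (sigmaBins < 1e-9) return(diag(n))
  ## very wide kernels: the reflected kernel converges to uniform smoothing
  if (sigmaBins >= 100 * n) return(matrix(1 / n, n, n))
  key <- paste(n, signif(sigmaBins, 12))
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  R <- max(1L, ceiling(4 * sigmaBins))
  off <- (-R):R
  w <- exp(-off^2 / (2 * sigmaBins^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    tg <- j + off
    ## fold indices into [1, n] by half-sample reflection
    for (r in seq_len(64)) {
      out <- tg < 1L | tg > n
      if (!any(out)) break
      tg <- ifelse(tg < 1L, 1L - tg, tg)
      tg <- ifelse(tg > n, 2L * n + 1L - tg, tg)
    }
    for (k in seq_along(tg)) K[tg[k], j] <- K[tg[k], j] + w[k]
  }
  .kernelCache[[key]] <- K
  K
}

## Uniform bin width of an axis (smoothing requires uniform bins).
uniformStep <- function(edges, label) {
  d <- diff(edges)
  if (max(d) - min(d) > 1e-8 * max(d))
    stop("smoothing requires uniform ", label, " bins")
  d[1]
}

#' Smooth a map with a 2-D Gaussian kernel
#'
#' Separable Gaussian filtering with bandwidths given in physical units (cm,
#' deg) and converted to bins. Boundaries use mirror (half-sample reflection)
#' handling, which conserves the map's total mass exactly and leaves
#' constant maps unchanged; theta is treated as bounded, not circular.
#'
#' @param values numeric matrix (z bins x theta bins).
#' @param grid the \code{\link{gridSpec}} the map lives on (uniform bins).
#' @param bw a \code{\link{bandwidths}} object.
#' @return smoothed matrix of the same dimensions.
#' @examples
#' g <- defaultGrid()
#' m <- matrix(0, gridDim(g)[1], gridDim(g)[2]); m[20, 30] <- 1
#' sum(smoothMap(m, g, bandwidths(4, 6)))  # 1: mass conserved
#' @export
smoothMap <- function(values, grid, bw) {
  stopIfNot(is(bw, "Bandwidths"), "bw must be a Bandwidths object")
  d <- gridDim(grid)
  stopIfNot(all(dim(values) == d), "values dimensions must match the grid")
  dz <- uniformStep(grid@zEdges, "z")
  dtt <- uniformStep(grid@thetaEdges, "theta")
  Kz <- gaussKernelMatrix(d[1], bw@sigmaZ / dz)
  Kt <- gaussKernelMatrix(d[2], bw@sigmaTheta / dtt)
  Kz %*% values %*% t(Kt)
}

## Precompute bilinear interpolation weights for field lookup at (z, theta)
## query points: indices of the four surrounding bin centers and the
## fractional weights, clamped at the grid edges.
interpWeights <- function(grid, z, theta) {
  axis <- function(x, centers) {
    x <- pmin(pmax(x, centers[1]), centers[length(centers)])
    i <- findInterval(x, centers)
    i <- pmin(pmax(i, 1L), length(centers) - 1L)
    w <- (x - centers[i]) / (centers[i + 1] - centers[i])
    list(i = i, w = w)
  }
  az <- axis(z, zCenters(grid))
  at <- axis(theta, thetaCenters(grid))
  list(iz = az$i, wz = az$w, it = at$i, wt = at$w)
}

applyInterp <- function(values, w) {
  n <- nrow(values)
  v11 <- values[w$iz + (w$it - 1L) * n]
  v21 <- values[w$iz + 1L + (w$it - 1L) * n]
  v12 <- values[w$iz + w$it * n]
  v22 <- values[w$iz + 1L + w$it * n]
  (1 - w$wz) * ((1 - w$wt) * v11 + w$wt * v12) +
    w$wz * ((1 - w$wt) * v21 + w$wt * v22)
}

#' Look up a field along a trajectory
#'
#' Evaluates an estimated field at arbitrary (z, theta) points, by bilinear
#' interpolation between bin centers (clamped at the edges; the default,
#' which removes binning artifacts from the cross-validation error) or by
#' nearest-bin lookup (strict formula parity with the binned estimate).
#'
#' @param field a \code{\link{FieldEstimate}} or a plain matrix with a
#'   \code{grid} argument.
#' @param z,theta numeric query coordinates.
#' @param method "bilinear" or "nearest".
#' @param grid required when \code{field} is a plain matrix.
#' @return numeric vector of field values.
#' @export
fieldLookup <- function(field, z, theta, method = c("bilinear", "nearest"),
                        grid = NULL) {
  method <- match.arg(method)
  if (is(field, "FieldEstimate")) {
    grid <- field@grid
    values <- field@values
  } else values <- field
  stopIfNot(!is.null(grid), "grid must be supplied for plain matrices")
  if (method == "bilinear") {
    applyInterp(values, interpWeights(grid, z, theta))
  } else {
    zc <- pmin(pmax(z, min(grid@zEdges)), max(grid@zEdges))
    tc <- pmin(pmax(theta, min(grid@thetaEdges)), max(grid@thetaEdges))
    b <- frameBins(grid, zc, tc)
    values[cbind(b$iz, b$it)]
  }
}
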