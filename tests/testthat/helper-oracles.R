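## Independent brute-force oracles: explicit scalar loops, no shared code
## with the package implementation beyond the mathematical definitions.

bruteReflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

bruteKernel <- function(sigmaBins) {
  if (sigmaBins < 1e-9) return(list(off = 0L, w = 1))
  R <- max(1, ceiling(4 * sigmaBins))
  off <- (-R):R
  w <- exp(-off^2 / (2 * sigmaBins^2))
  list(off = off, w = w / sum(w))
}

bruteSmooth <- function(M, dz, dt, sz, st) {
  nz <- nrow(M); nt <- ncol(M)
  kz <- bruteKernel(sz / dz)
  kt <- bruteKernel(st / dt)
  out <- matrix(0, nz, nt)
  for (i in seq_len(nz)) for (j in seq_len(nt)) {
    if (M[i, j] == 0) next
    for (a in seq_along(kz$off)) for (b in seq_along(kt$off)) {
      ti <- bruteReflect(i + kz$off[a], nz)
      tj <- bruteReflect(j + kt$off[b], nt)
      out[ti, tj] <- out[ti, tj] + M[i, j] * kz$w[a] * kt$w[b]
    }
  }
  out
}

bruteEstimateField <- function(occ, sig, dz, dt, sz, st, lambda, fMean) {
  occF <- bruteSmooth(occ, dz, dt, sz, st)
  sigF <- bruteSmooth(sig, dz, dt, sz, st)
  out <- matrix(0, nrow(occ), ncol(occ))
  for (i in seq_len(nrow(occ))) for (j in seq_len(ncol(occ)))
    out[i, j] <- (sigF[i, j] + lambda * fMean) / (occF[i, j] + lambda)
  out
}

bruteCvError <- function(pred, actual, fMeanTrain) {
  num <- 0; den <- 0
  for (k in seq_along(actual)) {
    num <- num + (pred[k] - actual[k])^2
    den <- den + (actual[k] - fMeanTrain)^2
  }
  (num / length(actual)) / (den / length(actual))
}

bruteAuroc <- function(neg, pos) {
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

bruteLogPosterior <- function(response, fieldList, sigmas, prior) {
  nz <- nrow(prior); nt <- ncol(prior)
  out <- matrix(0, nz, nt)
  for (i in seq_len(nz)) for (j in seq_len(nt)) {
    s <- 0
    for (k in seq_along(response))
      s <- s - (fieldList[[k]][i, j] - response[k])^2 / (2 * sigmas[k]^2)
    out[i, j] <- s + log(prior[i, j])
  }
  out
}

## random BinnedMaps instance on a small grid
randomMapsInstance <- function(seed, maxDim = 8) {
  set.seed(seed)
  nz <- sample(2:maxDim, 1); nt <- sample(2:maxDim, 1)
  grid <- gridSpec(seq(0, by = runif(1, 0.5, 3), length.out = nz + 1),
                   seq(-30, by = runif(1, 1, 5), length.out = nt + 1))
  occ <- matrix(rpois(nz * nt, 2), nz, nt)
  sig <- matrix(rnorm(nz * nt), nz, nt) * (occ > 0)
  list(grid = grid,
       maps = new("BinnedMaps", occupancy = occ * 1.0, signal = sig,
                  grid = grid),
       bw = bandwidths(runif(1, 0.3, 4), runif(1, 0.5, 8)),
       lambda = runif(1, 0.1, 3), fMean = rnorm(1))
}
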