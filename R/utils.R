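## Small internal helpers shared across modules.

## Derive a reproducible child seed from a master seed. Kept below 2^31 so it
## is always representable as an R integer.
childSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.numeric(k) * 16807) %% 2147483646 + 1)
}

## Assign trials to cross-validation folds, stratified by choice so that left
## and right trials are balanced across folds. Returns an integer fold id per
## trial (parallel to `choices`).
makeFolds <- function(choices, nFolds, seed) {
  n <- length(choices)
  if (n < nFolds)
    stop("fewer trials (", n, ") than folds (", nFolds, ")")
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (cl in unique(choices)) {
      idx <- which(choices == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

## mean absolute deviation from the median (constant = 1), the dispersion
## summary used throughout the reports.
madAboutMedian <- function(x) {
  x <- x[is.finite(x)]
  stats::median(abs(x - stats::median(x)))
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
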