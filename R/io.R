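## Delimited-text round-tripping of sessions and JSON report writers. All
## floating point is written with 12 significant digits; files are plain
## CSV/JSON so runs can be diffed.

fmtCol <- function(x) {
  if (is.double(x)) sprintf("%.12g", x) else x
}

writeCsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmtCol), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

requireColumns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", file, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

#' Write a session to a directory of delimited-text files
#'
#' Writes \code{session.csv} (t, trial_id, z, theta), \code{trials.csv}
#' (trial_id, contrast, choice, correct, is_repeat), \code{traces.csv}
#' (frame plus one neuron_<k> column per neuron, if any),
#' \code{session_meta.json} (geometry, frame rate) and, when the session
#' carries a synthetic ground-truth population, \code{truth.json}.
#'
#' @param session a \code{\link{NavSession}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- trajectory(session)
  writeCsv(data.frame(t = traj$t, trial_id = traj$trialId, z = traj$z,
                      theta = traj$theta),
           file.path(dir, "session.csv"))
  tr <- trials(session)
  writeCsv(data.frame(trial_id = tr$trialId, contrast = tr$contrast,
                      choice = tr$choice, correct = tr$correct,
                      is_repeat = tr$isRepeat),
           file.path(dir, "trials.csv"))
  R <- responses(session)
  if (nrow(R) > 0) {
    tdf <- data.frame(frame = seq_len(ncol(R)))
    for (i in seq_len(nrow(R))) tdf[[paste0("neuron_", i)]] <- R[i, ]
    writeCsv(tdf, file.path(dir, "traces.csv"))
  }
  g <- geometry(session)
  writeJson(list(corridor_length = g@corridorLength,
                 heading_min = g@headingMin, heading_max = g@headingMax,
                 z_min = g@zMin, frame_rate = frameRate(session)),
            file.path(dir, "session_meta.json"))
  pop <- metadata(session)$population
  if (!is.null(pop))
    writeJson(list(neurons = pop), file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a session written by \code{\link{writeSession}}
#'
#' Malformed files raise a schema error naming the file and the missing
#' column. CRLF and LF line endings parse identically.
#'
#' @param dir the session directory.
#' @return A \code{\link{NavSession}} (with ground-truth population in
#'   \code{metadata} when \code{truth.json} is present).
#' @export
readSession <- function(dir) {
  sessFile <- file.path(dir, "session.csv")
  trialFile <- file.path(dir, "trials.csv")
  for (f in c(sessFile, trialFile))
    if (!file.exists(f)) stop("missing file: ", f)
  samples <- utils::read.csv(sessFile)
  requireColumns(samples, c("t", "trial_id", "z", "theta"), sessFile)
  tr <- utils::read.csv(trialFile)
  requireColumns(tr, c("trial_id", "contrast", "choice", "correct",
                       "is_repeat"), trialFile)
  geometry <- mazeGeometry()
  frameRate <- 7.5
  metaFile <- file.path(dir, "session_meta.json")
  if (file.exists(metaFile)) {
    m <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
    geometry <- mazeGeometry(m$corridor_length, m$heading_min,
                             m$heading_max, m$z_min)
    frameRate <- m$frame_rate
  }
  R <- NULL
  traceFile <- file.path(dir, "traces.csv")
  if (file.exists(traceFile)) {
    td <- utils::read.csv(traceFile)
    requireColumns(td, "frame", traceFile)
    neuronCols <- grep("^neuron_", names(td), value = TRUE)
    R <- t(as.matrix(td[neuronCols]))
  }
  pop <- NULL
  truthFile <- file.path(dir, "truth.json")
  if (file.exists(truthFile))
    pop <- as.data.frame(
      jsonlite::read_json(truthFile, simplifyVector = TRUE)$neurons)
  navSession(
    trials = data.frame(trialId = tr$trial_id, contrast = tr$contrast,
                        choice = tr$choice, correct = tr$correct,
                        isRepeat = tr$is_repeat),
    samples = data.frame(t = samples$t, trialId = samples$trial_id,
                         z = samples$z, theta = samples$theta),
    responses = R, geometry = geometry, frameRate = frameRate,
    population = pop)
}

## report writers used by the pipeline -------------------------------------

fieldsToJson <- function(fieldFits, grid) {
  list(
    grid = list(z_edges = grid@zEdges, theta_edges = grid@thetaEdges),
    neurons = lapply(fieldFits, function(ff) {
      f <- ff$field
      list(sigma_z = f@bandwidths@sigmaZ, sigma_theta = f@bandwidths@sigmaTheta,
           lambda = f@lambda, f_mean = f@fMean, cv_error = f@cvError,
           values = as.vector(t(f@values)))  # row-major, z outer
    }))
}

maskToCsv <- function(mask, path) {
  writeCsv(data.frame(z_lo = mask$zLo, z_hi = mask$zHi, auroc = mask$auroc,
                      excluded = mask$excluded), path)
}

sequencesToCsv <- function(seqs, prefix) {
  writeCsv(as.data.frame(seqs$left), paste0(prefix, "_left.csv"))
  writeCsv(as.data.frame(seqs$right), paste0(prefix, "_right.csv"))
  writeCsv(seqs$ordering, paste0(prefix, "_order.csv"))
}
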