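#' Construct a trial-epoched session
#'
#' Assembles an [EcogSession-class] from an epoched voltage array and
#' per-trial behavioral metadata. Most users will obtain sessions from
#' [simulateSession()] or from their own epoching code.
#'
#' @param voltages Trials x electrodes x samples numeric array (microvolts).
#' @param fs Sampling rate (Hz).
#' @param task Character per trial: `"detection"` or `"discrimination"`.
#' @param outcome Character per trial: `"correct"` or `"incorrect"`.
#' @param reactionTime Numeric per trial (ms), `NA` where no response.
#' @param markers Named integer sample indices: `cueOn`, `stim1On`,
#'   `stim1Off`, `stim2On`, `stim2Off`.
#' @param groundTruth Optional list (synthetic sessions).
#' @return An [EcogSession-class].
#' @export
ecogSession <- function(voltages, fs, task, outcome,
                        reactionTime = rep(NA_real_, length(task)),
                        markers, groundTruth = list()) {
  new("EcogSession", voltages = voltages, fs = fs,
      task = as.character(task), outcome = as.character(outcome),
      reactionTime = as.numeric(reactionTime),
      markers = vapply(markers, as.integer, 1L),
      groundTruth = groundTruth)
}

#' @rdname corstate-accessors
#' @aliases voltages,EcogSession-method
#' @export
setMethod("voltages", "EcogSession", function(x, ...) x@voltages)

#' @rdname corstate-accessors
#' @export
setMethod("samplingRate", "EcogSession", function(x, ...) x@fs)

#' @rdname corstate-accessors
#' @export
setMethod("taskLabels", "EcogSession", function(x, ...) x@task)

#' @rdname corstate-accessors
#' @export
setMethod("outcomes", "EcogSession", function(x, ...) x@outcome)

#' @rdname corstate-accessors
#' @export
setMethod("reactionTimes", "EcogSession", function(x, ...) x@reactionTime)

#' @rdname corstate-accessors
#' @export
setMethod("markers", "EcogSession", function(x, ...) x@markers)

#' @rdname corstate-accessors
#' @export
setMethod("groundTruth", "EcogSession", function(x, ...) x@groundTruth)

#' @rdname corstate-accessors
#' @export
setMethod("nTrials", "EcogSession", function(x, ...) dim(x@voltages)[1])

#' @rdname corstate-accessors
#' @export
setMethod("nElectrodes", "EcogSession", function(x, ...) dim(x@voltages)[2])

#' @rdname subsetSession
#' @aliases subsetSession,EcogSession-method
#' @export
setMethod("subsetSession", "EcogSession", function(x, trials = NULL,
                                                   electrodes = NULL) {
  nt <- dim(x@voltages)[1]
  ne <- dim(x@voltages)[2]
  ti <- if (is.null(trials)) seq_len(nt) else seq_len(nt)[trials]
  ei <- if (is.null(electrodes)) seq_len(ne) else seq_len(ne)[electrodes]
  gt <- x@groundTruth
  if (length(gt)) {
    if (!is.null(gt$latentLogPr)) gt$latentLogPr <- gt$latentLogPr[ti, ei, drop = FALSE]
    if (!is.null(gt$populationZ)) gt$populationZ <- gt$populationZ[ti]
    if (!is.null(gt$artifact)) gt$artifact <- gt$artifact[ti]
  }
  new("EcogSession", voltages = x@voltages[ti, ei, , drop = FALSE], fs = x@fs,
      task = x@task[ti], outcome = x@outcome[ti],
      reactionTime = x@reactionTime[ti], markers = x@markers,
      groundTruth = gt)
})

#' @describeIn EcogSession-class Summary display.
#' @param object An `EcogSession`.
#' @export
setMethod("show", "EcogSession", function(object) {
  d <- dim(object@voltages)
  tk <- table(object@task)
  cat(sprintf("EcogSession: %d trials x %d electrodes x %d samples at %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat("  tasks: ", paste(sprintf("%s (%d)", names(tk), tk), collapse = ", "), "\n", sep = "")
  cat(sprintf("  outcome: %d correct / %d incorrect\n",
              sum(object@outcome == "correct"), sum(object@outcome == "incorrect")))
  if (length(object@groundTruth))
    cat("  synthetic session with ground truth\n")
})

#' Behavioral table of a session
#'
#' One row per trial: task, outcome, reaction time and the artifact flag
#' (for synthetic sessions).
#'
#' @param session An [EcogSession-class].
#' @return A `data.frame`.
#' @export
behavioralTable <- function(session) {
  stopifnot(is(session, "EcogSession"))
  d <- data.frame(trial = seq_len(nTrials(session)),
                  task = session@task, outcome = session@outcome,
                  reactionTimeMs = session@reactionTime)
  if (!is.null(session@groundTruth$artifact))
    d$artifact <- session@groundTruth$artifact
  d
}

#' Export the behavioral table as CSV
#'
#' @param session An [EcogSession-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBehavioralTable <- function(session, path) {
  utils::write.csv(behavioralTable(session), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a session
#'
#' Thin RDS-based serialization for [EcogSession-class] objects.
#'
#' @param session An [EcogSession-class].
#' @param path File path.
#' @return `readSessionRds` returns the session; `writeSessionRds` returns
#'   `path` invisibly.
#' @export
writeSessionRds <- function(session, path) {
  stopifnot(is(session, "EcogSession"))
  saveRDS(session, path)
  invisible(path)
}

#' @rdname writeSessionRds
#' @export
readSessionRds <- function(path) {
  x <- readRDS(path)
  stopifnot(is(x, "EcogSession"))
  x
}

# run code under a local RNG stream without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
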