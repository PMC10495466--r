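#' Common-average reference
#'
#' Subtracts, at every sample of every trial, the mean signal of the
#' non-ictal electrode set (the referenced electrode included when it belongs
#' to the set) from each electrode. After referencing, the mean over the
#' non-ictal set is identically zero.
#'
#' @param session An [EcogSession-class].
#' @param nonictal Integer or logical index of non-ictal electrodes; defaults
#'   to all. Must select at least two electrodes.
#' @return The referenced [EcogSession-class].
#' @export
commonAverageReference <- function(session, nonictal = NULL) {
  stopifnot(is(session, "EcogSession"))
  ne <- nElectrodes(session)
  ni <- if (is.null(nonictal)) seq_len(ne) else seq_len(ne)[nonictal]
  if (length(ni) < 2) stop("need at least two non-ictal electrodes to reference")
  v <- session@voltages
  ref <- colMeans(aperm(v[, ni, , drop = FALSE], c(2, 1, 3)))   # trials x samples
  for (e in seq_len(ne)) v[, e, ] <- v[, e, ] - ref
  session@voltages <- v
  session
}

#' Remove line noise
#'
#' Zero-phase Chebyshev II band-stop filtering of the 60 Hz (by default) line
#' component from every trace of a session, or from a plain vector/matrix of
#' signals.
#'
#' @param x An [EcogSession-class], or a numeric vector / samples-x-signals
#'   matrix.
#' @param fs Sampling rate (Hz); taken from the session when `x` is one.
#' @param f0 Line frequency (Hz).
#' @param halfWidth Stopband half width (Hz).
#' @return Object of the same shape with the line component removed.
#' @export
removeLineNoise <- function(x, fs = NULL, f0 = 60, halfWidth = 0.6) {
  if (is(x, "EcogSession")) {
    spec <- designNotch(x@fs, f0, halfWidth)
    x@voltages <- .filter_session_array(x@voltages, spec)
    return(x)
  }
  stopifnot(!is.null(fs))
  filterSignal(x, designNotch(fs, f0, halfWidth))
}

#' Band-pass filter signals
#'
#' Zero-phase Chebyshev II band-pass filtering into the `f1`-`f2` Hz band
#' (designed per [designBandpass()]).
#'
#' @param x An [EcogSession-class], or a numeric vector / samples-x-signals
#'   matrix.
#' @param f1,f2 Band edges (Hz).
#' @param fs Sampling rate (Hz); taken from the session when `x` is one.
#' @return Object of the same shape, band-passed.
#' @export
bandpassFilter <- function(x, f1, f2, fs = NULL) {
  if (is(x, "EcogSession")) {
    spec <- .cached_bandpass(x@fs, c(f1, f2))
    x@voltages <- .filter_session_array(x@voltages, spec)
    return(x)
  }
  stopifnot(!is.null(fs))
  filterSignal(x, .cached_bandpass(fs, c(f1, f2)))
}

# filter a trials x electrodes x samples array trace by trace, batching one
# electrode's trials per kernel call
.filter_session_array <- function(v, spec, pad = NULL) {
  d <- dim(v)
  for (e in seq_len(d[2]))
    v[, e, ] <- t(filterSignal(t(v[, e, , drop = TRUE]), spec, pad))
  v
}

#' Detect epileptiform ("spiking") trials
#'
#' For each task and electrode, computes the threshold
#' `TH = mean + nStd * sd` of the absolute values of the raw signal over all
#' of that task's trials concatenated, then rejects every trial in which the
#' absolute signal exceeds TH (strictly) for at least `minFraction` of the
#' samples. An electrode is excluded outright when fewer than `minTrials`
#' clean trials survive in any task present in the session.
#'
#' @param session An [EcogSession-class] of raw (unnormalized) voltages.
#' @param tasks Tasks to process; defaults to all tasks present.
#' @param nStd Threshold SD multiplier.
#' @param minFraction Minimum supra-threshold sample fraction for rejection.
#' @param minTrials Minimum surviving trials per task for an electrode to be
#'   retained.
#' @return A [RejectionReport-class].
#' @export
detectSpikingTrials <- function(session, tasks = NULL, nStd = 3,
                                minFraction = 0.05, minTrials = 50L) {
  stopifnot(is(session, "EcogSession"))
  if (is.null(tasks)) tasks <- unique(session@task)
  stopifnot(all(tasks %in% session@task))
  nt <- nTrials(session)
  ne <- nElectrodes(session)
  th <- matrix(NA_real_, ne, length(tasks),
               dimnames = list(NULL, tasks))
  frac <- matrix(NA_real_, nt, ne)
  for (tk in tasks) {
    ti <- which(session@task == tk)
    for (e in seq_len(ne)) {
      a <- abs(matrix(session@voltages[ti, e, ], nrow = length(ti)))
      thr <- mean(a) + nStd * stats::sd(as.numeric(a))
      th[e, tk] <- thr
      frac[ti, e] <- rowMeans(a > thr)
    }
  }
  rejected <- !is.na(frac) & frac >= minFraction
  excluded <- logical(ne)
  reason <- character(ne)
  for (e in seq_len(ne)) {
    surv <- vapply(tasks, function(tk) {
      ti <- session@task == tk
      sum(ti) - sum(rejected[ti, e])
    }, 0L)
    if (any(surv < minTrials)) {
      excluded[e] <- TRUE
      reason[e] <- sprintf("fewer than %d clean trials in task '%s'",
                           minTrials, tasks[which.min(surv)])
    }
  }
  new("RejectionReport", tasks = tasks, threshold = th,
      exceedFraction = replace(frac, is.na(frac), 0),
      rejected = rejected, electrodeExcluded = excluded, reason = reason,
      params = list(nStd = nStd, minFraction = minFraction,
                    minTrials = as.integer(minTrials)))
}

#' @rdname corstate-accessors
#' @export
setMethod("rejectedTrials", "RejectionReport", function(x, ...) {
  which(apply(x@rejected, 1, any))
})

#' @rdname corstate-accessors
#' @export
setMethod("excludedElectrodes", "RejectionReport", function(x, ...) {
  which(x@electrodeExcluded)
})

#' @describeIn RejectionReport-class Summary display.
#' @param object A `RejectionReport`.
#' @export
setMethod("show", "RejectionReport", function(object) {
  cat(sprintf(
    "RejectionReport (TH = mean + %g sd of |signal|, reject at >= %g%% samples):\n",
    object@params$nStd, 100 * object@params$minFraction))
  cat(sprintf("  %d/%d trials rejected on at least one electrode\n",
              sum(apply(object@rejected, 1, any)), nrow(object@rejected)))
  cat(sprintf("  %d/%d electrodes excluded (< %d clean trials in a task)\n",
              sum(object@electrodeExcluded), ncol(object@rejected),
              object@params$minTrials))
})

#' As-data.frame view of a rejection report
#'
#' @param x A [RejectionReport-class].
#' @param ... Unused.
#' @return Long-format `data.frame` (trial, electrode, exceed fraction,
#'   rejected).
#' @export
setMethod("as.data.frame", "RejectionReport", function(x, ...) {
  nt <- nrow(x@rejected); ne <- ncol(x@rejected)
  data.frame(trial = rep(seq_len(nt), ne),
             electrode = rep(seq_len(ne), each = nt),
             exceedFraction = as.numeric(x@exceedFraction),
             rejected = as.logical(x@rejected))
})

#' Drop rejected trials and excluded electrodes
#'
#' Removes excluded electrodes, and every trial rejected on more than
#' `voteFraction` of the retained electrodes, returning the cleaned session.
#' Epileptiform discharges are spatially widespread, so a genuine event is
#' rejected on most electrodes at once, whereas isolated single-electrode
#' threshold crossings reflect ordinary amplitude fluctuations of that
#' electrode; the vote keeps the rectangular trials x electrodes layout the
#' downstream analyses use without discarding a trial for every isolated
#' crossing. Per-electrode analyses that want exactly the per-electrode trial
#' sets can use the report's `rejected` matrix directly.
#'
#' @param session The [EcogSession-class] the report was computed from.
#' @param report A [RejectionReport-class].
#' @param voteFraction Fraction of retained electrodes that must reject a
#'   trial for it to be dropped (0 reproduces the any-electrode rule).
#' @return A cleaned [EcogSession-class].
#' @export
cleanSession <- function(session, report, voteFraction = 0.5) {
  stopifnot(is(session, "EcogSession"), is(report, "RejectionReport"))
  keepE <- !report@electrodeExcluded
  if (!any(keepE)) stop("all electrodes excluded")
  badT <- rowMeans(report@rejected[, keepE, drop = FALSE]) > voteFraction
  subsetSession(session, trials = !badT, electrodes = keepE)
}

#' Z-transform each channel
#'
#' Normalizes every electrode to zero mean and unit variance over all
#' retained trials' samples. Used when channels are pooled into population
#' statistics so that no electrode dominates through its recording gain; the
#' power ratio itself is scale invariant and does not require it.
#'
#' @param session An [EcogSession-class].
#' @return The normalized [EcogSession-class]. Channels with zero variance
#'   are left untouched and reported via a warning.
#' @export
zscoreChannels <- function(session) {
  stopifnot(is(session, "EcogSession"))
  v <- session@voltages
  degenerate <- integer(0)
  for (e in seq_len(dim(v)[2])) {
    x <- v[, e, ]
    s <- stats::sd(as.numeric(x))
    if (s == 0) {
      degenerate <- c(degenerate, e)
      next
    }
    v[, e, ] <- (x - mean(x)) / s
  }
  if (length(degenerate))
    warning("zero-variance channel(s) left unnormalized: ",
            paste(degenerate, collapse = ", "))
  session@voltages <- v
  session
}
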