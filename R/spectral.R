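#' Compute the pre-stimulus power ratio
#'
#' For every trial and electrode, band-passes the whole epoch into the low
#' and high bands with the zero-phase Chebyshev II filters and takes the
#' ratio of the mean voltage-squared power of the two band-passed signals
#' over the analysis window (by default the 400 ms preceding stimulus-1
#' onset, which is interior to the epoch so filter edge effects never touch
#' the analyzed samples). High PR marks the synchronized cortical state.
#'
#' @param session An [EcogSession-class] (already referenced/line-filtered as
#'   appropriate; PR is scale invariant, so channel z-scoring is not
#'   required).
#' @param window Length-2 numeric (ms) relative to stimulus-1 onset.
#' @param lowBand,highBand Band edges (Hz).
#' @return A [PowerRatioTable-class]. Entries whose high-band power is
#'   numerically zero are flagged and set to `NA`.
#' @examples
#' s <- simulateSession(generatorConfig(nElectrodes = 2, nTrials = 12,
#'                                      fs = 500, artifactRate = 0),
#'                      task = "detection")
#' prt <- computePowerRatio(s)
#' summary(as.numeric(powerRatio(prt)))
#' @export
computePowerRatio <- function(session, window = c(-400, 0),
                              lowBand = c(2.5, 12), highBand = c(12, 80)) {
  stopifnot(is(session, "EcogSession"), length(window) == 2,
            window[1] < window[2])
  fs <- session@fs
  on1 <- session@markers[["stim1On"]]
  i0 <- on1 + as.integer(round(window[1] * fs / 1000))
  i1 <- on1 + as.integer(round(window[2] * fs / 1000)) - 1L
  ns <- dim(session@voltages)[3]
  if (i0 < 1 || i1 > ns) stop("analysis window falls outside the epoch")
  idx <- i0:i1
  specLow <- .cached_bandpass(fs, lowBand)
  specHigh <- .cached_bandpass(fs, highBand)
  nt <- nTrials(session)
  ne <- nElectrodes(session)
  pr <- matrix(NA_real_, nt, ne)
  for (e in seq_len(ne)) {
    x <- t(matrix(session@voltages[, e, ], nrow = nt))   # samples x trials
    pLow <- colMeans(filterSignal(x, specLow)[idx, , drop = FALSE]^2)
    pHigh <- colMeans(filterSignal(x, specHigh)[idx, , drop = FALSE]^2)
    pr[, e] <- pLow / pHigh
  }
  flagged <- !is.finite(pr) | pr <= 0
  pr[flagged] <- NA_real_
  lp <- pr
  lp[!flagged] <- log(pr[!flagged])
  new("PowerRatioTable", pr = pr, logPr = lp, window = window,
      lowBand = lowBand, highBand = highBand, flagged = flagged,
      task = session@task)
}

#' @rdname corstate-accessors
#' @export
setMethod("powerRatio", "PowerRatioTable", function(x, ...) x@pr)

#' @rdname corstate-accessors
#' @export
setMethod("logPowerRatio", "PowerRatioTable", function(x, ...) x@logPr)

#' @rdname corstate-accessors
#' @export
setMethod("nTrials", "PowerRatioTable", function(x, ...) nrow(x@pr))

#' @rdname corstate-accessors
#' @export
setMethod("nElectrodes", "PowerRatioTable", function(x, ...) ncol(x@pr))

#' @rdname corstate-accessors
#' @export
setMethod("taskLabels", "PowerRatioTable", function(x, ...) x@task)

#' @describeIn PowerRatioTable-class Summary display.
#' @param object A `PowerRatioTable`.
#' @export
setMethod("show", "PowerRatioTable", function(object) {
  cat(sprintf(
    "PowerRatioTable: %d trials x %d electrodes, bands %g-%g / %g-%g Hz, window [%g, %g] ms\n",
    nrow(object@pr), ncol(object@pr), object@lowBand[1], object@lowBand[2],
    object@highBand[1], object@highBand[2], object@window[1], object@window[2]))
  cat(sprintf("  mean PR %.2f (flagged entries: %d)\n",
              mean(object@pr, na.rm = TRUE), sum(object@flagged)))
})

#' Long-format view of a power-ratio table
#'
#' @param x A [PowerRatioTable-class].
#' @param ... Unused.
#' @return `data.frame` with trial, electrode, task, pr, logPr.
#' @export
setMethod("as.data.frame", "PowerRatioTable", function(x, ...) {
  nt <- nrow(x@pr); ne <- ncol(x@pr)
  data.frame(trial = rep(seq_len(nt), ne),
             electrode = rep(seq_len(ne), each = nt),
             task = rep(x@task, ne),
             pr = as.numeric(x@pr), logPr = as.numeric(x@logPr))
})

# ---- multitaper machinery ----------------------------------------------

# discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem; cached per (n, nw, k)
.dpss_cache <- new.env(parent = emptyenv())

.dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- i[-1] * (n - i[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tj <- tap[, j]
    tap[, j] <- tj / sqrt(sum(tj^2)) * if (sum(tj) < 0) -1 else 1
  }
  .dpss_cache[[key]] <- tap
  tap
}

# multitaper power of the columns of x (samples x traces); rows of the
# result index one-sided frequencies 0..fs/2
.mtpower <- function(x, fs, nw = 3, k = 5) {
  n <- nrow(x)
  tap <- .dpss(n, nw, min(k, 2 * nw - 1))
  nf <- n %/% 2 + 1
  p <- matrix(0, nf, ncol(x))
  for (j in seq_len(ncol(tap))) {
    Y <- stats::mvfft(x * tap[, j])
    p <- p + Mod(Y[seq_len(nf), , drop = FALSE])^2
  }
  list(freqs = (seq_len(nf) - 1) * fs / n, power = p / ncol(tap))
}

# z-score the rows (grid points) of a points x trials matrix across trials;
# zero-variance points get z = 0 and a degeneracy flag
.ztrials <- function(p) {
  mu <- rowMeans(p)
  sd <- sqrt(pmax(rowMeans(p^2) - mu^2, 0) * ncol(p) / max(1, ncol(p) - 1))
  deg <- sd <= .Machine$double.eps * pmax(1, abs(mu))
  z <- (p - mu) / ifelse(deg, 1, sd)
  z[deg, ] <- 0
  list(z = z, degenerate = deg)
}

#' Z-scored multitaper spectrum by condition
#'
#' Computes a per-trial multitaper power spectrum of the analysis window at
#' each electrode, z-scores the power across all trials at each frequency
#' (so the all-trial mean is zero at every grid point), and averages the
#' z-scores within each condition. With two conditions the condition means
#' are mirror images weighted by condition size:
#' `sum_c n_c * mean_c(f) = 0` at every frequency, exactly.
#'
#' @param session An [EcogSession-class].
#' @param conditionLabels Factor-like per trial (e.g. `outcomes(session)`).
#' @param window Length-2 numeric (ms) relative to stimulus-1 onset.
#' @param nw Time-bandwidth product of the tapers.
#' @param k Number of tapers.
#' @return A [SpectralEstimate-class].
#' @export
zscoredSpectrum <- function(session, conditionLabels, window = c(-400, 0),
                            nw = 3, k = 5) {
  stopifnot(is(session, "EcogSession"),
            length(conditionLabels) == nTrials(session))
  lab <- as.factor(conditionLabels)
  if (any(table(lab) < 2))
    stop("each condition needs at least 2 trials for a z-scored spectrum")
  fs <- session@fs
  on1 <- session@markers[["stim1On"]]
  idx <- (on1 + as.integer(round(window[1] * fs / 1000))):
    (on1 + as.integer(round(window[2] * fs / 1000)) - 1L)
  stopifnot(idx[1] >= 1, idx[length(idx)] <= dim(session@voltages)[3])
  nt <- nTrials(session)
  ne <- nElectrodes(session)
  first <- .mtpower(t(matrix(session@voltages[, 1, ], nrow = nt))[idx, ,
                                                                  drop = FALSE],
                    fs, nw, k)
  nf <- length(first$freqs)
  z <- array(0, dim = c(nt, nf, ne))
  deg <- array(FALSE, dim = c(nf, ne))
  for (e in seq_len(ne)) {
    p <- if (e == 1) first$power else
      .mtpower(t(matrix(session@voltages[, e, ], nrow = nt))[idx, ,
                                                             drop = FALSE],
               fs, nw, k)$power
    zz <- .ztrials(p)
    z[, , e] <- t(zz$z)
    deg[, e] <- zz$degenerate
  }
  condMeans <- lapply(levels(lab), function(l) {
    m <- apply(z[lab == l, , , drop = FALSE], c(2, 3), mean)
    dimnames(m) <- NULL
    m
  })
  names(condMeans) <- levels(lab)
  popMean <- lapply(condMeans, rowMeans)
  new("SpectralEstimate", freqs = first$freqs, times = numeric(0), z = z,
      conditionMeans = condMeans, populationMean = popMean,
      conditionN = stats::setNames(as.integer(table(lab)), levels(lab)),
      degenerate = deg)
}

#' Z-scored multitaper spectrogram by condition
#'
#' As [zscoredSpectrum()], applied to a sliding window stepped through the
#' epoch; the z-scoring is done independently at every time-frequency point
#' along the trial dimension. Only condition means are retained.
#'
#' @param session An [EcogSession-class].
#' @param conditionLabels Factor-like per trial.
#' @param windowMs Sliding window length (ms).
#' @param stepMs Step between window centers (ms).
#' @param nw,k Multitaper parameters.
#' @return A [SpectralEstimate-class] with `times` set to window centers (ms
#'   relative to stimulus-1 onset).
#' @export
zscoredSpectrogram <- function(session, conditionLabels, windowMs = 200,
                               stepMs = 50, nw = 3, k = 5) {
  stopifnot(is(session, "EcogSession"),
            length(conditionLabels) == nTrials(session))
  lab <- as.factor(conditionLabels)
  if (any(table(lab) < 2)) stop("each condition needs at least 2 trials")
  fs <- session@fs
  nt <- nTrials(session)
  ne <- nElectrodes(session)
  ns <- dim(session@voltages)[3]
  wlen <- as.integer(round(windowMs * fs / 1000))
  step <- as.integer(round(stepMs * fs / 1000))
  starts <- seq(1L, ns - wlen + 1L, by = step)
  on1 <- session@markers[["stim1On"]]
  times <- (starts + wlen / 2 - on1) * 1000 / fs
  nb <- length(starts)
  nf <- wlen %/% 2 + 1
  condMeans <- lapply(levels(lab), function(l) array(0, dim = c(nf, nb, ne)))
  names(condMeans) <- levels(lab)
  deg <- array(FALSE, dim = c(nf, nb, ne))
  freqs <- NULL
  for (e in seq_len(ne)) {
    xe <- t(matrix(session@voltages[, e, ], nrow = nt))   # samples x trials
    for (b in seq_len(nb)) {
      seg <- xe[starts[b]:(starts[b] + wlen - 1L), , drop = FALSE]
      mt <- .mtpower(seg, fs, nw, k)
      if (is.null(freqs)) freqs <- mt$freqs
      zz <- .ztrials(mt$power)
      deg[, b, e] <- zz$degenerate
      for (l in levels(lab))
        condMeans[[l]][, b, e] <- rowMeans(zz$z[, lab == l, drop = FALSE])
    }
  }
  popMean <- lapply(condMeans, function(a) apply(a, c(1, 2), mean))
  new("SpectralEstimate", freqs = freqs, times = times,
      z = array(0, dim = c(0, 0, 0)), conditionMeans = condMeans,
      populationMean = popMean,
      conditionN = stats::setNames(as.integer(table(lab)), levels(lab)),
      degenerate = deg)
}

#' @describeIn SpectralEstimate-class Summary display.
#' @param object A `SpectralEstimate`.
#' @export
setMethod("show", "SpectralEstimate", function(object) {
  kind <- if (length(object@times)) "spectrogram" else "spectrum"
  cat(sprintf("SpectralEstimate (%s): %d frequencies", kind,
              length(object@freqs)))
  if (length(object@times)) cat(sprintf(" x %d time bins", length(object@times)))
  cat(sprintf(", conditions: %s\n",
              paste(sprintf("%s (n=%d)", names(object@conditionN),
                            object@conditionN), collapse = ", ")))
})

#' Trial-lag autocorrelation of the power ratio
#'
#' Normalized autocorrelation of each electrode's trial-ordered log-PR
#' series at lags `1..maxLag`, with a per-lag population test (Wilcoxon
#' signed rank of the per-electrode coefficients against zero),
#' Bonferroni-corrected over lags. Lag 0 is included and equals 1 by
#' definition. A flat, non-significant autocorrelation indicates that the
#' ongoing state fluctuates at random from trial to trial.
#'
#' @param x A [PowerRatioTable-class] or a trials x electrodes matrix of
#'   (log) PR values in trial order.
#' @param maxLag Largest lag (trials).
#' @return A list of class `"prAutocorrelation"`: `perElectrode` (lags x
#'   electrodes matrix), `summary` (data.frame with lag, mean coefficient,
#'   raw and Bonferroni-corrected p).
#' @export
prAutocorrelation <- function(x, maxLag = 20) {
  m <- if (is(x, "PowerRatioTable")) x@logPr else as.matrix(x)
  nt <- nrow(m)
  if (nt < maxLag + 10)
    stop("need at least maxLag + 10 trials for a stable autocorrelation")
  ac <- apply(m, 2, function(v) {
    if (stats::sd(v) == 0) stop("constant PR series: autocorrelation undefined")
    stats::acf(v, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })                                           # (maxLag + 1) x electrodes
  lags <- 0:maxLag
  pv <- vapply(seq_len(maxLag), function(l) {
    wilcoxonSignedRank(ac[l + 1, ])@pValue
  }, 0)
  data <- data.frame(lag = lags, meanAcf = rowMeans(ac),
                     p = c(NA, pv), pBonferroni = c(NA, bonferroni(pv, maxLag)))
  structure(list(perElectrode = ac, summary = data, maxLag = maxLag),
            class = "prAutocorrelation")
}

#' @export
print.prAutocorrelation <- function(x, ...) {
  cat(sprintf("PR trial autocorrelation, lags 1..%d:\n", x$maxLag))
  sig <- sum(x$summary$pBonferroni < 0.05, na.rm = TRUE)
  cat(sprintf("  mean |acf| %.3f; %d lag(s) significant after Bonferroni\n",
              mean(abs(x$summary$meanAcf[-1])), sig))
  invisible(x)
}

#' Subset a power-ratio table by trials
#'
#' @param x A [PowerRatioTable-class].
#' @param i Trial index (integer or logical).
#' @param j,...,drop Ignored (electrodes are retained).
#' @return A [PowerRatioTable-class] with the selected trials.
#' @export
setMethod("[", "PowerRatioTable", function(x, i, j, ..., drop = FALSE) {
  new("PowerRatioTable", pr = x@pr[i, , drop = FALSE],
      logPr = x@logPr[i, , drop = FALSE], window = x@window,
      lowBand = x@lowBand, highBand = x@highBand,
      flagged = x@flagged[i, , drop = FALSE], task = x@task[i])
})
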