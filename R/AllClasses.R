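#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib corstate, .registration = TRUE
NULL

#' Zero-phase Chebyshev Type II filter specification
#'
#' Holds a digital Chebyshev Type II band-pass or band-stop design as
#' second-order sections, together with the design parameters. Objects are
#' created by [designBandpass()] or [designNotch()], applied with
#' [filterSignal()], and always used forward-backward (zero phase), so the
#' stated stopband attenuation is per pass and doubles in effect.
#'
#' @slot kind `"pass"` or `"stop"`.
#' @slot passband Numeric length-2, passband edge frequencies (Hz) the design
#'   meets at `ripple` dB.
#' @slot stopband Numeric length-2, stopband edge frequencies (Hz) at which
#'   the attenuation reaches `attenuation` dB.
#' @slot attenuation Stopband attenuation per pass (dB).
#' @slot ripple Maximum passband attenuation per pass at the passband edges (dB).
#' @slot order Order of the low-pass prototype (the digital filter has twice
#'   as many poles).
#' @slot sos Second-order-section matrix (`n x 6`, columns b0 b1 b2 a0 a1 a2).
#' @slot fs Sampling rate (Hz).
#' @export
setClass("FilterSpec",
  representation(kind = "character", passband = "numeric",
                 stopband = "numeric", attenuation = "numeric",
                 ripple = "numeric", order = "integer", sos = "matrix",
                 fs = "numeric"))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("pass", "stop")) msg <- c(msg, "kind must be 'pass' or 'stop'")
  if (any(diff(object@stopband) <= 0)) msg <- c(msg, "stopband edges must be increasing")
  if (object@attenuation <= 0) msg <- c(msg, "attenuation must be positive")
  if (max(object@stopband, object@passband) >= object@fs / 2)
    msg <- c(msg, "band edges must lie below the Nyquist frequency")
  if (ncol(object@sos) != 6) msg <- c(msg, "sos must have 6 columns")
  if (length(msg)) msg else TRUE
})

#' Trial-epoched multi-electrode ECoG session
#'
#' The unit of data the pipeline consumes: an epoched voltage array with
#' per-trial behavioral metadata and within-epoch event markers. Epochs share
#' a common layout, so markers are sample indices valid for every trial. For
#' synthetic sessions produced by [simulateSession()] the `groundTruth` slot
#' stores the latent state that generated each trial.
#'
#' @slot voltages 3-D numeric array, trials x electrodes x samples (microvolts).
#' @slot fs Sampling rate (Hz).
#' @slot task Character per trial, `"detection"` or `"discrimination"`.
#' @slot outcome Character per trial, `"correct"` or `"incorrect"`.
#' @slot reactionTime Numeric per trial (ms); `NA` for incorrect
#'   (non-responded) trials.
#' @slot markers Named integer vector of sample indices (1-based): `cueOn`,
#'   `stim1On`, `stim1Off`, `stim2On`, `stim2Off`. The pre-stimulus window is
#'   the 400 ms preceding `stim1On`; the cue sounds at its start. `stim2*`
#'   markers describe the test stimulus of discrimination trials.
#' @slot groundTruth List for synthetic sessions (latent log power ratios,
#'   population state, artifact flags, generator configuration); empty
#'   otherwise.
#' @export
setClass("EcogSession",
  representation(voltages = "array", fs = "numeric", task = "character",
                 outcome = "character", reactionTime = "numeric",
                 markers = "integer", groundTruth = "list"))

setValidity("EcogSession", function(object) {
  msg <- character()
  d <- dim(object@voltages)
  if (length(d) != 3) return("voltages must be a trials x electrodes x samples array")
  nt <- d[1]; ns <- d[3]
  for (s in c("task", "outcome", "reactionTime"))
    if (length(slot(object, s)) != nt)
      msg <- c(msg, sprintf("%s must have one entry per trial", s))
  if (!all(object@task %in% c("detection", "discrimination")))
    msg <- c(msg, "task entries must be 'detection' or 'discrimination'")
  if (!all(object@outcome %in% c("correct", "incorrect")))
    msg <- c(msg, "outcome entries must be 'correct' or 'incorrect'")
  if (any(!is.na(object@reactionTime) & object@outcome == "incorrect"))
    msg <- c(msg, "reaction time must be NA for incorrect trials")
  need <- c("cueOn", "stim1On", "stim1Off", "stim2On", "stim2Off")
  if (!all(need %in% names(object@markers)))
    msg <- c(msg, paste("markers must include", paste(need, collapse = ", ")))
  else {
    mk <- object@markers[need]
    if (any(diff(mk) <= 0)) msg <- c(msg, "markers must be strictly increasing")
    if (mk["stim2Off"] > ns) msg <- c(msg, "markers must lie inside the epoch")
    if (mk["stim1On"] - round(0.4 * object@fs) < 1)
      msg <- c(msg, "the 400 ms pre-stimulus window must fit inside the epoch")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic session generator
#'
#' All tunable parameters of [simulateSession()]. Defaults are calibrated so
#' that a default session reproduces the statistical structure of human
#' temporal-lobe ECoG during detection/discrimination tasks: log-normal
#' trial-wise power ratio with mean PR 10.62, a latent state shared across
#' electrodes giving a same-state probability near 0.61 at 50 electrodes,
#' task-dependent coupling of state to outcome with opposite signs, evoked
#' responses positively correlated with pre-stimulus state, and occasional
#' epileptiform bursts. See the methods vignette for the calibration.
#'
#' @slot nElectrodes Number of electrodes.
#' @slot nTrials Number of trials per task.
#' @slot fs Sampling rate (Hz); must exceed 160 Hz to resolve the 80 Hz band
#'   edge.
#' @slot epoch Named durations (ms): `preCue`, `preStim`, `stim`, `delay`,
#'   `test`, `response`.
#' @slot logprMean,logprSd Mean and SD of the per-electrode trial-wise log
#'   power ratio (natural-log scale).
#' @slot stateSharing Fraction in [0, 1] of log-PR variance shared across
#'   electrodes through the global latent state.
#' @slot detectionCoupling,discriminationCoupling Logistic slopes of
#'   P(correct) on the standardized population log-PR.
#' @slot detectionRate,discriminationRate Baseline proportion correct at the
#'   average state.
#' @slot evokedGain Slope of evoked log-power on the standardized
#'   per-electrode log-PR (natural-log units per z).
#' @slot evokedNoiseSd SD of trial-wise evoked log-power noise.
#' @slot evokedLogPowerBase Baseline evoked transient log-power
#'   (log microvolts squared).
#' @slot testMinusTargetSlope Slope (dB per population z) of the test-minus-
#'   target evoked difference on the (negated) population state.
#' @slot testMinusTargetOffset Constant offset (dB) of that difference.
#' @slot testMinusTargetNoiseSd Trial-wise noise SD (dB) of that difference.
#' @slot rtBase,rtSlope,rtNoiseSd Reaction-time model (ms): baseline, slope
#'   per population z (sign follows the task coupling), and noise SD.
#' @slot artifactRate Probability that a trial carries an epileptiform burst.
#' @slot artifactAmplitude Burst amplitude in units of the trace SD.
#' @slot artifactFraction Burst duration as a fraction of the epoch.
#' @slot seed Integer seed governing all draws.
#' @export
setClass("GeneratorConfig",
  representation(nElectrodes = "integer", nTrials = "integer", fs = "numeric",
                 epoch = "numeric", logprMean = "numeric", logprSd = "numeric",
                 stateSharing = "numeric", detectionCoupling = "numeric",
                 discriminationCoupling = "numeric", detectionRate = "numeric",
                 discriminationRate = "numeric", evokedGain = "numeric",
                 evokedNoiseSd = "numeric", evokedLogPowerBase = "numeric",
                 testMinusTargetSlope = "numeric",
                 testMinusTargetOffset = "numeric",
                 testMinusTargetNoiseSd = "numeric",
                 rtBase = "numeric", rtSlope = "numeric", rtNoiseSd = "numeric",
                 artifactRate = "numeric", artifactAmplitude = "numeric",
                 artifactFraction = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nElectrodes < 1) msg <- c(msg, "nElectrodes must be >= 1")
  if (object@nTrials < 2) msg <- c(msg, "nTrials must be >= 2")
  if (object@fs <= 2 * 80) msg <- c(msg, "fs must exceed 160 Hz (twice the 80 Hz band edge)")
  need <- c("preCue", "preStim", "stim", "delay", "test", "response")
  if (!all(need %in% names(object@epoch)))
    msg <- c(msg, paste("epoch must name", paste(need, collapse = ", ")))
  else if (any(object@epoch[need] <= 0)) msg <- c(msg, "all epoch durations must be positive")
  if (object@stateSharing < 0 || object@stateSharing > 1)
    msg <- c(msg, "stateSharing must lie in [0, 1]")
  if (object@artifactRate < 0 || object@artifactRate >= 1)
    msg <- c(msg, "artifactRate must lie in [0, 1)")
  if (object@logprSd <= 0) msg <- c(msg, "logprSd must be positive")
  # logistic couplings that saturate P(correct) within +-3 z signal
  # misconfiguration rather than a usable study condition
  for (tk in c("detection", "discrimination")) {
    b <- slot(object, paste0(tk, "Coupling"))
    a <- stats::qlogis(slot(object, paste0(tk, "Rate")))
    p <- stats::plogis(a + c(-3, 3) * abs(b))
    if (p[1] < 0.005 || p[2] > 0.995)
      msg <- c(msg, sprintf("%sCoupling saturates outcome probabilities within 3 SD of state", tk))
  }
  if (length(msg)) msg else TRUE
})

#' Epileptiform trial rejection report
#'
#' Result of [detectSpikingTrials()]: the per-electrode, per-task amplitude
#' threshold TH = mean + 3 sd of the absolute concatenated signal, the
#' fraction of supra-threshold samples per trial, the rejected trials
#' (fraction >= 5%), and electrodes excluded for retaining fewer than 50
#' clean trials in either task.
#'
#' @slot tasks Tasks the thresholds were computed over.
#' @slot threshold Electrodes x tasks matrix of TH (microvolts).
#' @slot exceedFraction Trials x electrodes matrix: fraction of samples with
#'   |signal| > TH (each trial judged under its own task's threshold).
#' @slot rejected Trials x electrodes logical matrix.
#' @slot electrodeExcluded Logical per electrode.
#' @slot reason Character per electrode ("" if retained).
#' @slot params List of the rule parameters (`nStd`, `minFraction`,
#'   `minTrials`).
#' @export
setClass("RejectionReport",
  representation(tasks = "character", threshold = "matrix",
                 exceedFraction = "matrix", rejected = "matrix",
                 electrodeExcluded = "logical", reason = "character",
                 params = "list"))

setValidity("RejectionReport", function(object) {
  msg <- character()
  if (any(object@exceedFraction < 0 | object@exceedFraction > 1))
    msg <- c(msg, "exceedFraction entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pre-stimulus power-ratio table
#'
#' Trials x electrodes matrix of the pre-stimulus power ratio PR (mean
#' voltage-squared power of the zero-phase band-passed signal in the low band
#' divided by that in the high band) and its natural log. Produced by
#' [computePowerRatio()]. Trials with numerically vanishing high-band power
#' are flagged.
#'
#' @slot pr Trials x electrodes positive matrix.
#' @slot logPr Natural log of `pr`.
#' @slot window Length-2 numeric, analysis window (ms) relative to stimulus-1
#'   onset; the default pre-stimulus window is `c(-400, 0)`.
#' @slot lowBand,highBand Length-2 numeric band edges (Hz).
#' @slot flagged Logical matrix of undefined entries.
#' @slot task Character per trial (carried from the session).
#' @export
setClass("PowerRatioTable",
  representation(pr = "matrix", logPr = "matrix", window = "numeric",
                 lowBand = "numeric", highBand = "numeric",
                 flagged = "matrix", task = "character"))

setValidity("PowerRatioTable", function(object) {
  msg <- character()
  ok <- !object@flagged
  if (any(object@pr[ok] <= 0)) msg <- c(msg, "pr must be positive where not flagged")
  if (max(abs(object@logPr[ok] - log(object@pr[ok])), 0) > 1e-8)
    msg <- c(msg, "logPr must equal log(pr)")
  if (length(msg)) msg else TRUE
})

#' Low/high cortical state labels
#'
#' Median-split state labels per trial: per electrode (PR above that
#' electrode's median across trials means "high") and for the electrode
#' population (median split of the across-electrode mean of the 0-1
#' normalized PR). Produced by [labelStates()].
#'
#' @slot labels Trials x electrodes logical matrix, `TRUE` = high PR.
#' @slot populationLabel Logical per trial, `TRUE` = high population PR.
#' @slot normalizedPr Trials x electrodes matrix, PR normalized to [0, 1]
#'   within each electrode.
#' @slot degenerateElectrodes Logical per electrode: all-equal PR, split
#'   undefined.
#' @slot task Character per trial.
#' @export
setClass("StateLabelTable",
  representation(labels = "matrix", populationLabel = "logical",
                 normalizedPr = "matrix", degenerateElectrodes = "logical",
                 task = "character"))

#' Multitaper spectral estimate with trial z-scores
#'
#' Per-trial multitaper power on a frequency (x time) grid, z-scored across
#' trials at each grid point and electrode, with condition means. Because the
#' z-scoring removes the all-trial mean at each grid point, condition means
#' weighted by condition size sum to zero exactly. Produced by
#' [zscoredSpectrum()] and [zscoredSpectrogram()].
#'
#' @slot freqs Frequency grid (Hz).
#' @slot times Time-bin centers (ms, relative to stimulus-1 onset); empty for
#'   plain spectra.
#' @slot z Trials x freqs x electrodes array of z-scored power (empty for
#'   spectrograms, which keep only condition means).
#' @slot conditionMeans Named list per condition: freqs x electrodes matrix
#'   (or freqs x times x electrodes array).
#' @slot populationMean Named list per condition: mean over electrodes.
#' @slot conditionN Named integer vector of condition sizes.
#' @slot degenerate Logical array marking zero-variance grid points (z set
#'   to 0).
#' @export
setClass("SpectralEstimate",
  representation(freqs = "numeric", times = "numeric", z = "array",
                 conditionMeans = "list", populationMean = "list",
                 conditionN = "integer", degenerate = "array"))

#' Evoked-response table
#'
#' Broad-band evoked power (dB) during the stimulus windows, referenced to
#' each electrode's session-wide mean pre-stimulus broad-band power so the
#' reference cancels in test-minus-target differences. Produced by
#' [evokedAnalysis()].
#'
#' @slot targetDb Trials x electrodes matrix, stimulus-1 evoked power (dB).
#' @slot testDb Trials x electrodes matrix, stimulus-2 evoked power (dB; `NA`
#'   for detection trials).
#' @slot diffDb `testDb - targetDb` (dB).
#' @slot referencePower Per-electrode reference power (microvolts squared).
#' @slot task Character per trial.
#' @export
setClass("EvokedTable",
  representation(targetDb = "matrix", testDb = "matrix", diffDb = "matrix",
                 referencePower = "numeric", task = "character"))

#' Cross-validated decoder result
#'
#' Distribution of 5-fold cross-validated Fisher-LDA accuracies over balanced
#' subsampling iterations, with the empirical p-value defined as the fraction
#' of iterations with accuracy below chance (0.5). Produced by
#' [decodeOutcome()].
#'
#' @slot accuracies Accuracy per iteration.
#' @slot nIterations Number of iterations.
#' @slot subsampleSize Trials drawn per class per iteration.
#' @slot nFeatures Feature dimension.
#' @slot pValue Fraction of iterations with accuracy < 0.5.
#' @slot seed Seed used.
#' @export
setClass("DecoderResult",
  representation(accuracies = "numeric", nIterations = "integer",
                 subsampleSize = "integer", nFeatures = "integer",
                 pValue = "numeric", seed = "integer"))

setValidity("DecoderResult", function(object) {
  msg <- character()
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hypothesis test result
#'
#' Uniform container for the rank tests used throughout the pipeline, with
#' explicit sidedness, pairing, sample size, and multiplicity correction.
#'
#' @slot statistic Test statistic.
#' @slot pValue P-value (corrected if `correction != "none"`).
#' @slot alternative `"two.sided"`, `"greater"` or `"less"`.
#' @slot method Test family (e.g. `"wilcoxon-signed-rank"`).
#' @slot n Sample size(s).
#' @slot correction `"none"` or `"bonferroni"`.
#' @slot familySize Family size used by the correction.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", pValue = "numeric",
                 alternative = "character", method = "character",
                 n = "integer", correction = "character",
                 familySize = "integer"))

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    "pValue must lie in [0, 1]" else TRUE
})
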