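# Shared fixtures, built once per test run and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# default-calibration two-task session (30 electrodes keep runtime moderate),
# cleaned and with its PR table and labels attached
fixtureSession <- function() {
  fixture("session", function() {
    cfg <- generatorConfig(nElectrodes = 30, nTrials = 100, seed = 7)
    s <- simulateSession(cfg)
    rep <- detectSpikingTrials(s)
    sc <- cleanSession(s, rep)
    keep <- rowMeans(rep@rejected) <= 0.5
    prt <- computePowerRatio(sc)
    list(raw = s, report = rep, session = sc, keep = keep,
         pr = prt, labels = suppressWarnings(labelStates(prt)))
  })
}

# small, fast session for structural tests (fs = 500 keeps filtering cheap)
fixtureSmall <- function() {
  fixture("small", function() {
    simulateSession(generatorConfig(nElectrodes = 4, nTrials = 24, fs = 500,
                                    artifactRate = 0, seed = 9))
  })
}

# PowerRatioTable wrapped around a plain matrix, for label/contrast tests
makePrTable <- function(pr, task = rep("detection", nrow(pr)),
                        window = c(-400, 0)) {
  pr <- as.matrix(pr)
  new("PowerRatioTable", pr = pr, logPr = log(pr), window = window,
      lowBand = c(2.5, 12), highBand = c(12, 80),
      flagged = matrix(FALSE, nrow(pr), ncol(pr)), task = task)
}

# session whose epochs are filled from a samples x trials generator function,
# same value on every electrode unless a per-electrode function is given
makeToneSession <- function(traceFun, nTrials = 6, nElectrodes = 2, fs = 1000,
                            task = rep("detection", nTrials),
                            outcome = rep(c("correct", "incorrect"),
                                          length.out = nTrials)) {
  epoch <- c(preCue = 400, preStim = 400, stim = 200, delay = 200,
             test = 200, response = 400)
  mk <- corstate:::.epoch_markers(epoch, fs)
  ns <- as.integer(round(sum(epoch) * fs / 1000))
  v <- array(0, dim = c(nTrials, nElectrodes, ns))
  for (t in seq_len(nTrials)) for (e in seq_len(nElectrodes))
    v[t, e, ] <- traceFun(ns, t, e)
  ecogSession(v, fs, task, outcome,
              reactionTime = ifelse(outcome == "correct", 500, NA_real_),
              markers = mk)
}

# FFT band-power integration over the analysis window: the independent
# oracle against which the time-domain band-pass PR is checked
fftBandPowerRatio <- function(x, fs, lowBand = c(2.5, 12),
                              highBand = c(12, 80)) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inBand <- function(b) half & f >= b[1] & f <= b[2]
  sum(p[inBand(lowBand)]) / sum(p[inBand(highBand)])
}
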