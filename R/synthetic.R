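#' Create a generator configuration
#'
#' Builds a [GeneratorConfig-class] with defaults calibrated to the
#' statistics this pipeline is designed to measure in human temporal-lobe
#' ECoG (see the methods vignette for each choice):
#' \itemize{
#'   \item trial-wise PR is log-normal with mean PR
#'     `exp(logprMean + logprSd^2 / 2) = 10.62`;
#'   \item `stateSharing = 0.13` puts the electrode-versus-population
#'     same-state probability near 0.61 for 50 electrodes (closed form
#'     `1/2 + asin(rho)/pi`, `rho = s / sqrt(s + (1 - s) / nE)`);
#'   \item outcome couplings `+0.6` (detection) and `-0.6` (discrimination)
#'     reproduce a performance split of roughly 53% vs 74% between low- and
#'     high-state trials, with opposite task signs;
#'   \item the evoked transient couples to the per-electrode state so the
#'     PR-versus-evoked-power Pearson correlation averages about 0.3, and the
#'     test-minus-target difference averages about +0.2 dB in low-state and
#'     about -0.1 dB in high-state discrimination trials;
#'   \item 5% of trials carry an epileptiform burst large and long enough to
#'     trip the amplitude rejection rule.
#' }
#'
#' @param nElectrodes,nTrials,fs,epoch,logprMean,logprSd,stateSharing
#'   See [GeneratorConfig-class].
#' @param detectionCoupling,discriminationCoupling,detectionRate,discriminationRate
#'   Outcome model; rates are the baseline proportions correct.
#' @param evokedGain,evokedNoiseSd,evokedLogPowerBase Evoked-response model.
#' @param testMinusTargetSlope,testMinusTargetOffset,testMinusTargetNoiseSd
#'   Test-minus-target evoked difference model (dB).
#' @param rtBase,rtSlope,rtNoiseSd Reaction-time model (ms).
#' @param artifactRate,artifactAmplitude,artifactFraction Epileptiform burst
#'   model.
#' @param seed Integer seed.
#' @return A validated [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(nElectrodes = 4, nTrials = 20)
#' cfg
#' @export
generatorConfig <- function(nElectrodes = 50L, nTrials = 120L, fs = 1000,
                            epoch = c(preCue = 400, preStim = 400, stim = 200,
                                      delay = 200, test = 200, response = 400),
                            logprMean = log(10.62) - 0.5^2 / 2, logprSd = 0.5,
                            stateSharing = 0.13,
                            detectionCoupling = 0.6,
                            discriminationCoupling = -0.6,
                            detectionRate = 0.6438,
                            discriminationRate = 0.5583,
                            evokedGain = 0.45, evokedNoiseSd = 0.55,
                            evokedLogPowerBase = log(600),
                            testMinusTargetSlope = 0.42,
                            testMinusTargetOffset = 0.08,
                            testMinusTargetNoiseSd = 0.2,
                            rtBase = 600, rtSlope = 40, rtNoiseSd = 150,
                            artifactRate = 0.05, artifactAmplitude = 8,
                            artifactFraction = 0.1, seed = 1L) {
  new("GeneratorConfig", nElectrodes = as.integer(nElectrodes),
      nTrials = as.integer(nTrials), fs = fs, epoch = epoch,
      logprMean = logprMean, logprSd = logprSd, stateSharing = stateSharing,
      detectionCoupling = detectionCoupling,
      discriminationCoupling = discriminationCoupling,
      detectionRate = detectionRate, discriminationRate = discriminationRate,
      evokedGain = evokedGain, evokedNoiseSd = evokedNoiseSd,
      evokedLogPowerBase = evokedLogPowerBase,
      testMinusTargetSlope = testMinusTargetSlope,
      testMinusTargetOffset = testMinusTargetOffset,
      testMinusTargetNoiseSd = testMinusTargetNoiseSd,
      rtBase = rtBase, rtSlope = rtSlope, rtNoiseSd = rtNoiseSd,
      artifactRate = artifactRate, artifactAmplitude = artifactAmplitude,
      artifactFraction = artifactFraction, seed = as.integer(seed))
}

#' @describeIn GeneratorConfig-class Compact display.
#' @param object A `GeneratorConfig`.
#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d electrodes x %d trials/task at %g Hz, epoch %g ms\n",
    object@nElectrodes, object@nTrials, object@fs, sum(object@epoch)))
  cat(sprintf("  log-PR N(%.3f, %.2f), state sharing %.2f, couplings %+.2f / %+.2f\n",
              object@logprMean, object@logprSd, object@stateSharing,
              object@detectionCoupling, object@discriminationCoupling))
  cat(sprintf("  artifact rate %.2f, seed %d\n", object@artifactRate, object@seed))
})

# marker sample indices for an epoch layout at sampling rate fs
.epoch_markers <- function(epoch, fs) {
  ms <- function(x) as.integer(round(x * fs / 1000))
  pc <- ms(epoch[["preCue"]]); ps <- ms(epoch[["preStim"]])
  st <- ms(epoch[["stim"]]); dl <- ms(epoch[["delay"]]); te <- ms(epoch[["test"]])
  c(cueOn = pc + 1L, stim1On = pc + ps + 1L, stim1Off = pc + ps + st,
    stim2On = pc + ps + st + dl + 1L, stim2Off = pc + ps + st + dl + te)
}

# Hermitian-symmetric complex Gaussian spectrum shaped by `mag`, one column
# per trace; its inverse FFT is real band-limited Gaussian noise
.shaped_spectrum <- function(n, m, mag) {
  nyq <- n %/% 2
  act <- which(mag[2:nyq] > 1e-4 * max(mag)) + 1L
  Z <- matrix(0 + 0i, n, m)
  nf <- length(act) * m
  Z[act, ] <- complex(real = stats::rnorm(nf),
                      imaginary = stats::rnorm(nf)) * mag[act]
  Z[1, ] <- stats::rnorm(m) * mag[1]
  if (n %% 2 == 0) Z[nyq + 1, ] <- stats::rnorm(m) * mag[nyq + 1]
  Z[n + 2L - act, ] <- Conj(Z[act, ])
  Z
}

# cosine-ramped envelope for an evoked transient of `len` samples
.transient_env <- function(len, fs) {
  ramp <- max(2L, as.integer(round(0.01 * fs)))
  env <- rep(1, len)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  env[seq_len(ramp)] <- up
  env[len + 1 - seq_len(ramp)] <- rev(up)
  env
}

# add epileptiform bursts (3 Hz alternating square wave at `amplitude` times
# the per-electrode trace SD, covering `fraction` of the epoch) to the given
# trials, across all electrodes; consumes RNG draws for burst positions
.add_bursts <- function(volt, trials, fs, amplitude, fraction) {
  ns <- dim(volt)[3]
  ne <- dim(volt)[2]
  blen <- max(2L, as.integer(round(fraction * ns)))
  shape <- sign(sin(2 * pi * 3 * (seq_len(blen) - 1) / fs))
  shape[shape == 0] <- 1
  starts <- sample.int(ns - blen + 1L, length(trials), replace = TRUE)
  sds <- apply(volt, 2, function(m) stats::sd(as.numeric(m)))  # per-electrode SD
  for (i in seq_along(trials)) {
    idx <- starts[i]:(starts[i] + blen - 1L)
    for (e in seq_len(ne))
      volt[trials[i], e, idx] <- volt[trials[i], e, idx] + amplitude * sds[e] * shape
  }
  volt
}

#' Simulate a multi-electrode trial-epoched session
#'
#' Generates an [EcogSession-class] whose statistics follow the generator's
#' latent-state model. Per trial, a global latent state and per-electrode
#' deviations give each electrode a log-normal power ratio with variance
#' fraction `stateSharing` shared across electrodes. Each trace is the sum of
#' two band-limited Gaussian noise components, shaped in the frequency domain
#' by the squared magnitude response of the same zero-phase Chebyshev II
#' band-pass filters the analysis uses (so generator and analysis agree on
#' the band definitions by construction) and scaled so the realized
#' pre-stimulus-window band powers express the trial's latent PR exactly.
#' Outcome is Bernoulli with a logistic dependence on the standardized
#' population state (slope sign per task); correct trials get a reaction
#' time with the opposite-signed state dependence. Stimulus windows receive
#' additive broad-band transients whose log power grows with the electrode's
#' state by `evokedGain`; for discrimination trials the test transient
#' differs from the target by `testMinusTargetOffset +
#' testMinusTargetSlope * (-z)` dB plus noise. A fraction `artifactRate` of
#' trials receives an epileptiform burst. The result is bit-reproducible
#' given the configuration (including its seed).
#'
#' @param config A [GeneratorConfig-class].
#' @param task `"both"` (default; `nTrials` per task), `"detection"` or
#'   `"discrimination"`.
#' @return An [EcogSession-class] with ground truth.
#' @examples
#' s <- simulateSession(generatorConfig(nElectrodes = 3, nTrials = 10,
#'                                      fs = 500, seed = 7), task = "detection")
#' s
#' @export
simulateSession <- function(config,
                            task = c("both", "detection", "discrimination")) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  task <- match.arg(task)
  .with_seed(config@seed, {
    fs <- config@fs
    nE <- config@nElectrodes
    tasks <- switch(task,
      both = rep(c("detection", "discrimination"), each = config@nTrials),
      rep(task, config@nTrials))
    nT <- length(tasks)
    mk <- .epoch_markers(config@epoch, fs)
    ns <- as.integer(round(sum(config@epoch) * fs / 1000))
    mu <- config@logprMean; sdl <- config@logprSd; s <- config@stateSharing

    # latent state: shared + private parts of the per-electrode log PR
    g <- stats::rnorm(nT)
    eps <- matrix(stats::rnorm(nT * nE), nT, nE)
    latent <- mu + sdl * (sqrt(s) * g + sqrt(1 - s) * eps)
    zPop <- (rowMeans(latent) - mu) / (sdl * sqrt(s + (1 - s) / nE))
    zElec <- (latent - mu) / sdl

    # behavioral outcome and reaction time from the population state
    coupling <- ifelse(tasks == "detection", config@detectionCoupling,
                       config@discriminationCoupling)
    baseRate <- ifelse(tasks == "detection", config@detectionRate,
                       config@discriminationRate)
    pCorrect <- stats::plogis(stats::qlogis(baseRate) + coupling * zPop)
    outcome <- ifelse(stats::runif(nT) < pCorrect, "correct", "incorrect")
    rt <- config@rtBase - config@rtSlope * sign(coupling) * zPop +
      stats::rnorm(nT, 0, config@rtNoiseSd)
    rt <- pmax(rt, 150)
    rt[outcome == "incorrect"] <- NA_real_

    # band-limited noise shaped by the analysis filters' zero-phase response
    fgrid <- pmin(0:(ns - 1), ns - (0:(ns - 1))) * fs / ns
    magLow <- Mod(frequencyResponse(.cached_bandpass(fs, c(2.5, 12)), fgrid))^2
    magHigh <- Mod(frequencyResponse(.cached_bandpass(fs, c(12, 80)), fgrid))^2
    # the analysis re-applies the zero-phase filter when measuring band
    # power; pre-compensate the targets by the resulting spectral shrinkage
    corrLow <- sum(magLow^2) / sum(magLow^4)
    corrHigh <- sum(magHigh^2) / sum(magHigh^4)
    win <- mk[["cueOn"]]:(mk[["stim1On"]] - 1L)   # 400 ms pre-stimulus window
    # synchronization redistributes power between the bands: low-band power
    # rises and high-band power falls with the state, with the total band
    # power held constant, as in synchronized/desynchronized cortical states
    totalPower <- 1100                             # microvolts^2, both bands
    s1 <- mk[["stim1On"]]:mk[["stim1Off"]]
    s2 <- mk[["stim2On"]]:mk[["stim2Off"]]
    env1 <- .transient_env(length(s1), fs)
    env2 <- .transient_env(length(s2), fs)
    disc <- which(tasks == "discrimination")

    volt <- array(0, dim = c(nT, nE, ns))
    evokedNoise <- matrix(stats::rnorm(nT * nE, 0, config@evokedNoiseSd), nT, nE)
    tmtNoise <- matrix(stats::rnorm(nT * nE, 0, config@testMinusTargetNoiseSd), nT, nE)
    for (e in seq_len(nE)) {
      # one complex inverse FFT yields both band components (real/imag parts)
      Z <- .shaped_spectrum(ns, nT, magLow) +
        1i * .shaped_spectrum(ns, nT, magHigh)
      comp <- stats::mvfft(Z, inverse = TRUE) / ns
      low <- Re(comp); high <- Im(comp)              # ns x nT
      highTarget <- totalPower / (exp(latent[, e]) + 1)
      lowTarget <- exp(latent[, e]) * highTarget * corrLow
      low <- low * rep(sqrt(lowTarget / colMeans(low[win, , drop = FALSE]^2)),
                       each = ns)
      high <- high * rep(sqrt(highTarget * corrHigh /
                                colMeans(high[win, , drop = FALSE]^2)),
                         each = ns)
      x <- low + high

      # evoked transients: broad-band noise bursts in the stimulus windows
      p1 <- exp(config@evokedLogPowerBase + config@evokedGain * zElec[, e] +
                  evokedNoise[, e])
      w1 <- matrix(stats::rnorm(length(s1) * nT), length(s1), nT) * env1
      w1 <- w1 * rep(sqrt(p1 / colMeans(w1^2)), each = length(s1))
      x[s1, ] <- x[s1, ] + w1
      if (length(disc)) {
        dDb <- config@testMinusTargetOffset +
          config@testMinusTargetSlope * (-zPop[disc]) + tmtNoise[disc, e]
        p2 <- p1[disc] * 10^(dDb / 10)
        w2 <- matrix(stats::rnorm(length(s2) * length(disc)), length(s2),
                     length(disc)) * env2
        w2 <- w2 * rep(sqrt(p2 / colMeans(w2^2)), each = length(s2))
        x[s2, disc] <- x[s2, disc] + w2
      }
      volt[, e, ] <- t(x)
    }

    artifact <- stats::runif(nT) < config@artifactRate
    if (any(artifact))
      volt <- .add_bursts(volt, which(artifact), fs,
                          config@artifactAmplitude, config@artifactFraction)

    ecogSession(volt, fs, tasks, outcome, rt, mk,
                groundTruth = list(latentLogPr = latent, populationZ = zPop,
                                   artifact = artifact, config = config))
  })
}

#' Inject epileptiform bursts into a session
#'
#' Adds high-amplitude bursts (3 Hz alternating square wave, `amplitudeFactor`
#' times the per-electrode trace SD, covering `burstFraction` of the epoch on
#' every electrode) to a random `rate` fraction of trials, and records the
#' affected trials in the session's ground truth. Used to exercise
#' [detectSpikingTrials()]: a burst exceeding 3 SD for at least 5% of the
#' epoch must be rejected by the threshold rule.
#'
#' @param session An [EcogSession-class].
#' @param rate Probability that a trial receives a burst; `rate = 0` returns
#'   the session unchanged.
#' @param amplitudeFactor Burst amplitude in trace SDs; must exceed 3.
#' @param burstFraction Burst duration as a fraction of the epoch; must be at
#'   least 0.05.
#' @param seed Integer seed (the draw is independent of the session's own
#'   seed).
#' @return The modified [EcogSession-class].
#' @export
injectArtifacts <- function(session, rate, amplitudeFactor = 8,
                            burstFraction = 0.1, seed = 1L) {
  stopifnot(is(session, "EcogSession"), rate >= 0, rate < 1)
  if (rate == 0) return(session)
  if (amplitudeFactor <= 3)
    stop("amplitudeFactor must exceed 3 (the rejection rule's SD multiplier)")
  if (burstFraction < 0.05)
    stop("burstFraction must be at least 0.05 to satisfy the rejection rule")
  .with_seed(seed, {
    flag <- stats::runif(nTrials(session)) < rate
    if (any(flag))
      session@voltages <- .add_bursts(session@voltages, which(flag),
                                      session@fs, amplitudeFactor,
                                      burstFraction)
    gt <- session@groundTruth
    gt$artifact <- if (is.null(gt$artifact)) flag else gt$artifact | flag
    session@groundTruth <- gt
    session
  })
}
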