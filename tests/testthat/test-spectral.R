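test_that("power ratio is scale invariant and saturates for in-band tones", {
  fs <- 1000
  # pure 8 Hz tone: virtually all power in the low band
  s <- makeToneSession(function(ns, t, e) sin(2 * pi * 8 * seq_len(ns) / fs),
                       nTrials = 3, nElectrodes = 1, fs = fs)
  expect_gt(min(powerRatio(computePowerRatio(s))), 1e3)
  # scaling the voltages leaves PR untouched
  s2 <- fixtureSmall()
  prA <- powerRatio(computePowerRatio(s2))
  s3 <- s2
  s3@voltages <- s3@voltages * 7.3
  expect_equal(powerRatio(computePowerRatio(s3)), prA, tolerance = 1e-6)
})

test_that("two-tone PR agrees with FFT band-power integration", {
  fs <- 1000
  # tone frequencies on the 2.5 Hz grid of the 400 ms window, so that both
  # the windowed mean square and the periodogram see whole cycles
  cases <- list(c(1.3, 0.7, 7.5, 40), c(1, 1, 5, 25), c(0.5, 2, 10, 60))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]; f1 <- cs[3]; f2 <- cs[4]
    s <- makeToneSession(function(ns, t, e) {
      tt <- seq_len(ns) / fs
      a * sin(2 * pi * f1 * tt + t) + b * sin(2 * pi * f2 * tt + 2 * t)
    }, nTrials = 4, nElectrodes = 1, fs = fs)
    prt <- computePowerRatio(s)
    mk <- markers(s)
    win <- (mk[["stim1On"]] - 400):(mk[["stim1On"]] - 1)
    for (t in 1:4) {
      oracle <- fftBandPowerRatio(voltages(s)[t, 1, win], fs)
      expect_equal(powerRatio(prt)[t, 1], oracle, tolerance = 0.1)
    }
  }
})

test_that("z-scored spectra obey the weighted-sum-zero identity", {
  s <- fixtureSmall()
  lab <- outcomes(s)
  est <- zscoredSpectrum(s, lab, window = c(-400, 0))
  n <- est@conditionN
  combo <- n[["correct"]] * est@conditionMeans[["correct"]] +
    n[["incorrect"]] * est@conditionMeans[["incorrect"]]
  expect_equal(max(abs(combo)), 0, tolerance = 1e-10)
  # balanced conditions give exact mirror symmetry
  balLab <- rep(c("a", "b"), length.out = nTrials(s))
  estB <- zscoredSpectrum(s, balLab)
  expect_equal(estB@conditionMeans[["a"]], -estB@conditionMeans[["b"]],
               tolerance = 1e-10)
  # single-trial conditions are refused
  expect_error(zscoredSpectrum(s, c("solo", rep("rest", nTrials(s) - 1))),
               "at least 2")
})

test_that("identical trials give zero z-scores with a degeneracy flag", {
  fs <- 500
  s <- makeToneSession(function(ns, t, e) sin(2 * pi * 6 * seq_len(ns) / fs),
                       nTrials = 6, nElectrodes = 1, fs = fs)
  est <- zscoredSpectrum(s, rep(c("x", "y"), 3))
  expect_true(all(est@degenerate))
  expect_equal(max(abs(est@z)), 0)
})

test_that("spectrogram z-scores vanish for a random split of stationary noise", {
  set.seed(31)
  fs <- 500
  s <- makeToneSession(function(ns, t, e) rnorm(ns), nTrials = 40,
                       nElectrodes = 3, fs = fs)
  lab <- sample(rep(c("a", "b"), 20))
  est <- zscoredSpectrogram(s, lab, windowMs = 200, stepMs = 100)
  nA <- est@conditionN[["a"]]
  # per-condition mean of n z-scores has SD 1/sqrt(n); population mean over
  # 3 electrodes is pooled, use the per-electrode bound
  expect_lt(max(abs(est@conditionMeans[["a"]])), 4 / sqrt(nA))
  combo <- nA * est@conditionMeans[["a"]] +
    est@conditionN[["b"]] * est@conditionMeans[["b"]]
  expect_equal(max(abs(combo)), 0, tolerance = 1e-10)
  expect_equal(length(est@times), dim(est@conditionMeans[["a"]])[2])
})

test_that("correct detection trials carry more pre-stimulus low-frequency power", {
  s <- simulateSession(generatorConfig(nElectrodes = 25, nTrials = 150,
                                       detectionCoupling = 1.2,
                                       artifactRate = 0, seed = 32),
                       task = "detection")
  est <- zscoredSpectrum(s, outcomes(s), window = c(-400, 0))
  lowRows <- est@freqs >= 2.5 & est@freqs <= 12
  lowPower <- mean(est@populationMean[["correct"]][lowRows])
  expect_gt(lowPower, 0)
  highRows <- est@freqs >= 20 & est@freqs <= 80
  expect_lt(mean(est@populationMean[["correct"]][highRows]), lowPower)
})

test_that("PR autocorrelation is flat for i.i.d. states and recovers AR(1)", {
  set.seed(33)
  # i.i.d. series: no lag survives Bonferroni
  iid <- matrix(rnorm(100 * 30), 100, 30)
  acIid <- prAutocorrelation(iid, maxLag = 10)
  expect_equal(acIid$summary$meanAcf[1], 1)        # lag 0 by definition
  expect_true(all(acIid$summary$pBonferroni[-1] > 0.05))
  # AR(1) with phi = 0.9: acf(l) ~ phi^l
  phi <- 0.9
  n <- 400
  ar <- sapply(1:20, function(e)
    as.numeric(arima.sim(list(ar = phi), n = n)))
  acAr <- prAutocorrelation(ar, maxLag = 5)
  expect_equal(acAr$summary$meanAcf[2], phi, tolerance = 0.05)
  expect_equal(acAr$summary$meanAcf[3], phi^2, tolerance = 0.07)
  expect_true(all(acAr$summary$pBonferroni[2:3] < 0.05))
  # degenerate input
  expect_error(prAutocorrelation(matrix(1, 60, 2), maxLag = 5), "constant")
  expect_error(prAutocorrelation(iid[1:15, ], maxLag = 10), "at least")
})
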