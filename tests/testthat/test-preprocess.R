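test_that("common-average referencing zeroes the non-ictal mean", {
  # two identical electrodes cancel exactly
  s <- makeToneSession(function(ns, t, e) sin(2 * pi * 5 * seq_len(ns) / 500),
                       nTrials = 3, nElectrodes = 2, fs = 500)
  r <- commonAverageReference(s)
  expect_equal(max(abs(voltages(r))), 0)
  # an antisymmetric pair {x, -x} has zero reference: signals unchanged
  s2 <- makeToneSession(function(ns, t, e)
    (if (e == 1) 1 else -1) * sin(2 * pi * 5 * seq_len(ns) / 500 + t),
    nTrials = 3, nElectrodes = 2, fs = 500)
  r2 <- commonAverageReference(s2)
  expect_equal(voltages(r2), voltages(s2), tolerance = 1e-12)
  # random channels: mean over the non-ictal set is zero at every sample,
  # and electrodes outside the set are referenced too
  set.seed(11)
  s3 <- makeToneSession(function(ns, t, e) rnorm(ns),
                        nTrials = 4, nElectrodes = 5, fs = 500)
  r3 <- commonAverageReference(s3, nonictal = 1:4)
  v <- voltages(r3)
  expect_equal(max(abs(apply(v[, 1:4, , drop = FALSE], c(1, 3), mean))), 0,
               tolerance = 1e-12)
  expect_equal(v[, 5, ],
               voltages(s3)[, 5, ] - apply(voltages(s3)[, 1:4, ], c(1, 3), mean),
               tolerance = 1e-12)
  expect_error(commonAverageReference(s3, nonictal = 2), "at least two")
})

test_that("spiking-trial detection applies the threshold rule exactly", {
  # degenerate constant signal: TH = 0 and the strict inequality rejects nothing
  s0 <- makeToneSession(function(ns, t, e) rep(0, ns), nTrials = 4,
                        nElectrodes = 2, fs = 500)
  rep0 <- detectSpikingTrials(s0)
  expect_equal(sum(rep0@rejected), 0)
  expect_equal(unname(rep0@threshold[, 1]), c(0, 0))

  # one trial with a 20x burst over 10% of its samples is the only rejection;
  # brute-force recount of the rule is the oracle
  set.seed(12)
  nT <- 100; ns <- 500
  v <- array(rnorm(nT * 1 * ns), dim = c(nT, 1, ns))
  burstIdx <- 101:150
  v[17, 1, burstIdx] <- 20 * rep(c(1, -1), length.out = length(burstIdx))
  mk <- corstate:::.epoch_markers(c(preCue = 100, preStim = 400, stim = 200,
                                    delay = 100, test = 100, response = 100), 500)
  s <- ecogSession(v, 500, rep("detection", nT), rep("correct", nT),
                   rep(500, nT), mk)
  rep1 <- detectSpikingTrials(s, minTrials = 5L)
  a <- abs(as.numeric(v))
  th <- mean(a) + 3 * sd(a)
  fracOracle <- sapply(seq_len(nT), function(t) mean(abs(v[t, 1, ]) > th))
  expect_equal(rep1@exceedFraction[, 1], fracOracle)
  expect_equal(which(rep1@rejected[, 1]), 17L)
  expect_equal(unname(rep1@threshold[1, 1]), th)

  # rejection is invariant to trial order (TH depends on the sample multiset)
  perm <- sample(nT)
  sPerm <- subsetSession(s, trials = perm)
  repP <- detectSpikingTrials(sPerm, minTrials = 5L)
  expect_equal(repP@exceedFraction[, 1], fracOracle[perm])
  expect_equal(unname(repP@threshold[1, 1]), th)
})

test_that("electrodes with too few clean trials are excluded", {
  set.seed(13)
  nT <- 20; ns <- 400
  v <- array(rnorm(nT * 2 * ns), dim = c(nT, 2, ns))
  # electrode 2: bursts on most trials, short enough (7.5% of the epoch) that
  # the threshold statistics are not dragged up past the burst amplitude
  for (t in 1:15) v[t, 2, 1:30] <- 30
  mk <- corstate:::.epoch_markers(c(preCue = 50, preStim = 400, stim = 150,
                                    delay = 50, test = 50, response = 100), 500)
  s <- ecogSession(v, 500, rep("detection", nT), rep("correct", nT),
                   rep(400, nT), mk)
  rep <- detectSpikingTrials(s, minTrials = 10L)
  expect_false(rep@electrodeExcluded[1])
  expect_true(rep@electrodeExcluded[2])
  expect_match(rep@reason[2], "fewer than 10")
  sc <- cleanSession(s, rep)
  expect_equal(nElectrodes(sc), 1L)
})

test_that("artifact injection produces trials the detector flags", {
  s <- fixtureSmall()
  # rate zero is a strict no-op
  expect_identical(voltages(injectArtifacts(s, rate = 0)), voltages(s))
  # full-rate injection: every trial flagged and every trial rejected
  s1 <- injectArtifacts(s, rate = 0.999, amplitudeFactor = 20,
                        burstFraction = 0.07, seed = 2)
  expect_true(all(groundTruth(s1)$artifact))
  rep1 <- detectSpikingTrials(s1, minTrials = 1L)
  expect_true(all(rep1@rejected))
  # reproducible given the seed, different under another seed
  s2a <- injectArtifacts(s, rate = 0.3, seed = 5)
  s2b <- injectArtifacts(s, rate = 0.3, seed = 5)
  s2c <- injectArtifacts(s, rate = 0.3, seed = 6)
  expect_identical(voltages(s2a), voltages(s2b))
  expect_false(identical(voltages(s2a), voltages(s2c)))
  expect_error(injectArtifacts(s, rate = 0.2, amplitudeFactor = 2), "exceed 3")
})

test_that("rejection matches generator ground truth at a high artifact rate", {
  s <- simulateSession(generatorConfig(nElectrodes = 6, nTrials = 60, fs = 500,
                                       artifactRate = 0.3, seed = 14))
  rep <- detectSpikingTrials(s, minTrials = 5L)
  truth <- which(groundTruth(s)$artifact)
  # bursts hit every electrode: each electrode's rejection set contains the
  # truth set, and the majority vote recovers it exactly
  for (e in seq_len(6))
    expect_true(all(truth %in% which(rep@rejected[, e])))
  expect_equal(which(rowMeans(rep@rejected) > 0.5), truth)
  sc <- cleanSession(s, rep)
  expect_equal(nTrials(sc), nTrials(s) - length(truth))
})

test_that("channel z-transform normalizes first and second moments", {
  set.seed(15)
  s <- makeToneSession(function(ns, t, e) 5 + 2 * rnorm(ns),
                       nTrials = 6, nElectrodes = 3, fs = 500)
  z <- zscoreChannels(s)
  for (e in 1:3) {
    x <- as.numeric(voltages(z)[, e, ])
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-12)
  }
  # idempotent up to floating tolerance
  z2 <- zscoreChannels(z)
  expect_equal(voltages(z2), voltages(z), tolerance = 1e-10)
  # zero-variance channel flagged, others still normalized
  sBad <- makeToneSession(function(ns, t, e)
    if (e == 1) rep(2, ns) else rnorm(ns), nTrials = 4, nElectrodes = 2,
    fs = 500)
  expect_warning(zb <- zscoreChannels(sBad), "zero-variance")
  expect_equal(sd(as.numeric(voltages(zb)[, 2, ])), 1, tolerance = 1e-12)
})

test_that("line-noise removal cleans a contaminated session", {
  fs <- 500
  s <- makeToneSession(function(ns, t, e) {
    tt <- seq_len(ns) / fs
    sin(2 * pi * 10 * tt) + 2 * sin(2 * pi * 60 * tt + t)
  }, nTrials = 3, nElectrodes = 2, fs = fs)
  r <- removeLineNoise(s)
  # the notch rings for ~0.5 s, a fair share of these epochs, so the
  # suppression achievable on epoched data is transient-limited (~15 dB);
  # judge the removal in the frequency domain and check the 10 Hz line is
  # untouched
  atFreq <- function(x, f0) {
    n <- length(x)
    fr <- (seq_len(n) - 1) * fs / n
    sum(Mod(fft(x))[abs(fr - f0) < 0.75]^2)
  }
  x0 <- voltages(s)[1, 1, ]
  x1 <- voltages(r)[1, 1, ]
  expect_lt(atFreq(x1, 60) / atFreq(x0, 60), 0.05)
  # the other electrode and trials are filtered too
  expect_lt(atFreq(voltages(r)[3, 2, ], 60) / atFreq(voltages(s)[3, 2, ], 60),
            0.05)
  expect_equal(atFreq(x1, 10) / atFreq(x0, 10), 1, tolerance = 0.05)
})
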