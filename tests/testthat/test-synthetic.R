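test_that("identical configuration yields bit-identical sessions", {
  cfg <- generatorConfig(nElectrodes = 3, nTrials = 20, fs = 500, seed = 21)
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(voltages(a), voltages(b))
  expect_identical(outcomes(a), outcomes(b))
  expect_identical(reactionTimes(a), reactionTimes(b))
  expect_identical(groundTruth(a)$latentLogPr, groundTruth(b)$latentLogPr)
  cfg2 <- generatorConfig(nElectrodes = 3, nTrials = 20, fs = 500, seed = 22)
  expect_false(identical(voltages(a), voltages(simulateSession(cfg2))))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulateSession(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("state sharing controls the latent structure at its extremes", {
  cfg1 <- generatorConfig(nElectrodes = 2, nTrials = 30, fs = 500,
                          stateSharing = 1, artifactRate = 0, seed = 23)
  lat <- groundTruth(simulateSession(cfg1))$latentLogPr
  expect_equal(lat[, 1], lat[, 2], tolerance = 1e-12)
  cfg0 <- generatorConfig(nElectrodes = 6, nTrials = 200, fs = 500,
                          stateSharing = 0, artifactRate = 0, seed = 24)
  lat0 <- groundTruth(simulateSession(cfg0))$latentLogPr
  cors <- cor(lat0)[upper.tri(diag(6))]
  expect_lt(max(abs(cors)), 0.2)
})

test_that("measured PR follows the configured log-normal state", {
  s <- simulateSession(generatorConfig(nElectrodes = 2, nTrials = 500,
                                       fs = 500, artifactRate = 0, seed = 25),
                       task = "detection")
  prt <- computePowerRatio(s)
  # closed-form log-normal mean exp(mu + sigma^2/2) = 10.62; the measured
  # value carries filter-shaping shrinkage of a few percent
  expect_equal(mean(powerRatio(prt)), 10.62, tolerance = 0.1)
  # the log PR passes a normality check
  expect_gt(shapiro.test(logPowerRatio(prt)[, 1])$p.value, 0.01)
  # right-skew on the raw scale
  pr <- as.numeric(powerRatio(prt))
  expect_gt(mean(pr), median(pr))
  # the measurement tracks the latent state tightly
  lat <- groundTruth(s)$latentLogPr
  expect_gt(cor(as.numeric(lat), as.numeric(logPowerRatio(prt))), 0.9)
})

test_that("task couplings imprint the expected signs on a default session", {
  fx <- fixtureSession()
  sc <- fx$session
  for (tk in c("detection", "discrimination")) {
    ti <- taskLabels(sc) == tk
    prt <- computePowerRatio(subsetSession(sc, trials = ti))
    ct <- prOutcomeContrast(prt, outcomes(sc)[ti])
    md <- median(ct$byElectrode$pctDiff, na.rm = TRUE)
    if (tk == "detection") expect_gt(md, 0) else expect_lt(md, 0)
  }
  # reaction times: faster in high-PR states for detection, the reverse for
  # discrimination
  det <- taskLabels(sc) == "detection"
  rtDet <- rtStateCorrelation(computePowerRatio(subsetSession(sc, trials = det)),
                              reactionTimes(sc)[det])
  expect_lt(median(rtDet$byElectrode$r), 0)
  dis <- !det
  rtDis <- rtStateCorrelation(computePowerRatio(subsetSession(sc, trials = dis)),
                              reactionTimes(sc)[dis])
  expect_gt(median(rtDis$byElectrode$r), 0)
})

test_that("misconfigured generators are rejected", {
  expect_error(generatorConfig(stateSharing = 1.2), "stateSharing")
  expect_error(generatorConfig(artifactRate = 1), "artifactRate")
  expect_error(generatorConfig(detectionCoupling = 5), "saturates")
  expect_error(generatorConfig(fs = 150), "160 Hz")
  expect_error(generatorConfig(nTrials = 1), "nTrials")
  expect_error(generatorConfig(logprSd = 0), "logprSd")
})

test_that("session containers enforce their invariants", {
  s <- fixtureSmall()
  mk <- markers(s)
  expect_true(all(diff(mk[c("cueOn", "stim1On", "stim1Off", "stim2On",
                            "stim2Off")]) > 0))
  # reaction time present only on correct trials
  expect_true(all(is.na(reactionTimes(s)[outcomes(s) == "incorrect"])))
  # malformed metadata is refused
  v <- voltages(s)
  expect_error(ecogSession(v, 500, taskLabels(s), rep("maybe", nTrials(s)),
                           reactionTimes(s), mk), "outcome")
  badRt <- reactionTimes(s)
  badRt[which(outcomes(s) == "incorrect")[1]] <- 300
  expect_error(ecogSession(v, 500, taskLabels(s), outcomes(s), badRt, mk),
               "reaction time")
  badMk <- mk
  badMk["stim1Off"] <- badMk["stim1On"] - 1L
  expect_error(ecogSession(v, 500, taskLabels(s), outcomes(s),
                           reactionTimes(s), badMk), "increasing")
})

test_that("behavioral table and session round trips are faithful", {
  s <- fixtureSmall()
  b <- behavioralTable(s)
  expect_equal(nrow(b), nTrials(s))
  expect_identical(b$outcome, outcomes(s))
  f <- tempfile(fileext = ".csv")
  writeBehavioralTable(s, f)
  b2 <- read.csv(f)
  expect_equal(b2$reactionTimeMs, b$reactionTimeMs)
  f2 <- tempfile(fileext = ".rds")
  writeSessionRds(s, f2)
  expect_identical(voltages(readSessionRds(f2)), voltages(s))
  unlink(c(f, f2))
})
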