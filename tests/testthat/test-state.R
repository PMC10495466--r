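test_that("median-split labels follow ranks, not values", {
  prt <- makePrTable(cbind(c(1, 2, 3, 4)))
  lab <- labelStates(prt)
  expect_equal(unname(stateLabels(lab)[, 1]), c(FALSE, FALSE, TRUE, TRUE))
  # even n with distinct values: exactly n/2 high
  set.seed(41)
  m <- matrix(rlnorm(40 * 3), 40, 3)
  lab2 <- labelStates(makePrTable(m))
  expect_equal(unname(colSums(stateLabels(lab2))), rep(20, 3))
  # invariance under monotone transforms (median split is rank-based)
  lab3 <- labelStates(makePrTable(exp(m)))
  expect_identical(stateLabels(lab3), stateLabels(lab2))
  # normalized PR spans [0, 1] per electrode
  expect_equal(unname(apply(lab2@normalizedPr, 2, range)),
               matrix(c(0, 1), 2, 3))
  # degenerate electrode flagged
  expect_warning(labelStates(makePrTable(cbind(m[, 1], rep(2, 40)))),
                 "degenerate")
})

test_that("same-state probability hits its deterministic extremes", {
  set.seed(42)
  base <- rlnorm(30)
  # electrode 1 reproduces the population series: probability 1
  prt <- makePrTable(cbind(base, base * 2, base * 3))
  lab <- labelStates(prt)
  res <- sameStateProbability(lab, 1, nPermutations = 0)
  expect_equal(res$probability, 1)
  # reversed ranks: probability 0
  rev1 <- max(base) + min(base) - base     # strictly rank-reversing
  prt2 <- makePrTable(cbind(rev1, base, base * 1.5))
  lab2 <- labelStates(prt2)
  expect_equal(sameStateProbability(lab2, 1, nPermutations = 0)$probability, 0)
  # shuffle null sits at chance
  null <- sameStateProbability(lab, 1, nPermutations = 500, seed = 3)
  expect_equal(null$chanceLevel, 0.5, tolerance = 0.03)
  # guard rails
  expect_error(sameStateProbability(lab, 1, populationSubset = c(1, 2)),
               "must not belong")
  expect_error(sameStateProbability(labelStates(makePrTable(cbind(rlnorm(10),
                                                                  rlnorm(10)))),
                                    1), "20 trials")
})

test_that("leave-one-out probabilities rise with state sharing", {
  mk <- function(sharing, seed) {
    s <- simulateSession(generatorConfig(nElectrodes = 10, nTrials = 150,
                                         fs = 500, stateSharing = sharing,
                                         artifactRate = 0, seed = seed),
                         task = "detection")
    mean(sameStateProbabilities(labelStates(computePowerRatio(s))))
  }
  p0 <- mk(0, 43)
  pMid <- mk(0.3, 43)
  pHi <- mk(0.9, 43)
  expect_equal(p0, 0.5, tolerance = 0.05)
  expect_true(p0 < pMid && pMid < pHi)
  expect_gt(pHi, 0.8)
})

test_that("performance by state recovers couplings and obeys identities", {
  set.seed(44)
  n <- 200
  m <- matrix(rlnorm(n * 5), n, 5)
  lab <- labelStates(makePrTable(m))
  # deterministic coupling: correct exactly on high-population-state trials
  outDet <- ifelse(populationLabels(lab), "correct", "incorrect")
  pf <- suppressWarnings(performanceByState(lab, outDet, nIterations = 200))
  expect_equal(pf$byBin$percentCorrect, c(0, 100))
  expect_lt(pf$bootstrap$p, 0.05)
  # outcomes independent of state: no significant difference
  outNull <- sample(rep(c("correct", "incorrect"), n / 2))
  pfNull <- performanceByState(lab, outNull, nIterations = 500, seed = 5)
  expect_gt(pfNull$bootstrap$p, 0.05)
  # weighted mean of bin performances equals overall performance
  w <- pfNull$byBin$n
  expect_equal(sum(w * pfNull$byBin$percentCorrect) / sum(w),
               100 * mean(outNull == "correct"), tolerance = 1e-10)
  # tertile variant partitions all trials
  pf3 <- performanceByState(lab, outNull, nBins = 3, nIterations = 100)
  expect_equal(sum(pf3$byBin$n), n)
})

test_that("PR outcome contrast computes percent differences exactly", {
  # mean PR 12.5 on correct vs 10 on incorrect -> +25%
  prt <- makePrTable(cbind(c(rep(12.5, 10), rep(10, 10))))
  out <- rep(c("correct", "incorrect"), each = 10)
  expect_error(prOutcomeContrast(prt, out), NA)
  ct <- suppressWarnings(prOutcomeContrast(prt, out))
  expect_equal(ct$byElectrode$pctDiff[1], 25)
  # electrodes missing a condition are skipped with a report
  prt2 <- makePrTable(matrix(rlnorm(20 * 2), 20, 2))
  out2 <- rep("correct", 20)
  expect_error(prOutcomeContrast(prt2, out2), "no electrode")
})

test_that("population contrast is significant under generator coupling", {
  fx <- fixtureSession()
  det <- taskLabels(fx$session) == "detection"
  prt <- computePowerRatio(subsetSession(fx$session, trials = det))
  ct <- prOutcomeContrast(prt, outcomes(fx$session)[det],
                          direction = "positive")
  expect_lt(pValue(ct$oneSided), 0.05)
  expect_lt(pValue(ct$twoSided), 0.05)
})

test_that("evoked analysis recovers exact and null couplings", {
  set.seed(45)
  n <- 60
  ne <- 8
  logPr <- matrix(rnorm(n * ne, 2, 0.5), n, ne)
  prt <- makePrTable(exp(logPr))
  # session whose stimulus-window power is exp(log PR) exactly: r = 1
  fs <- 500
  epoch <- c(preCue = 400, preStim = 400, stim = 200, delay = 200,
             test = 200, response = 400)
  mk <- corstate:::.epoch_markers(epoch, fs)
  ns <- as.integer(sum(epoch) * fs / 1000)
  v <- array(rep(1, n * ne * ns), dim = c(n, ne, ns))
  s1 <- mk[["stim1On"]]:mk[["stim1Off"]]
  for (t in seq_len(n)) for (e in seq_len(ne))
    v[t, e, s1] <- sqrt(exp(logPr[t, e]))
  s <- ecogSession(v, fs, rep("detection", n), rep("correct", n),
                   rep(400, n), mk)
  ev <- evokedAnalysis(s, prt)
  expect_equal(ev$correlation$r, rep(1, ne), tolerance = 1e-10)
  expect_lt(pValue(ev$rTest), 0.05)
  # stimulus power independent of PR: median r near zero, not significant
  set.seed(46)
  for (t in seq_len(n)) for (e in seq_len(ne))
    v[t, e, s1] <- exp(rnorm(1, 0, 0.3))
  sNull <- ecogSession(v, fs, rep("detection", n), rep("correct", n),
                       rep(400, n), mk)
  evNull <- evokedAnalysis(sNull, prt)
  expect_lt(abs(median(evNull$correlation$r)), 0.3)
})

test_that("evoked-state coupling is calibrated to its target correlation", {
  fx <- fixtureSession()
  ev <- evokedAnalysis(fx$session, fx$pr)
  # generator default evokedGain targets a population mean Pearson r of 0.3
  expect_lt(abs(mean(ev$correlation$r) - 0.3), 0.05)
  expect_lt(pValue(ev$rTest), 0.01)
})

test_that("test-minus-target split separates low and high states", {
  fx <- fixtureSession()
  dis <- taskLabels(fx$session) == "discrimination"
  sD <- subsetSession(fx$session, trials = dis)
  prtD <- computePowerRatio(sD)
  evD <- evokedAnalysis(sD, prtD)
  expect_gt(evD$stateSplit$lowDb, evD$stateSplit$highDb)
  expect_lt(pValue(evD$stateSplit$test), 0.05)
  # detection-only session has no second-stimulus difference by design
  det <- subsetSession(fx$session, trials = !dis)
  evDet <- evokedAnalysis(det, computePowerRatio(det))
  expect_null(evDet$stateSplit)
  expect_true(all(is.na(evDet$evoked@testDb)))
})

test_that("reaction-time correlation hits the monotone limit and the null", {
  n <- 40
  logPr <- rnorm(n, 2, 0.5)
  prt <- makePrTable(cbind(exp(logPr)))
  # RT strictly decreasing in PR: r = -1
  res <- rtStateCorrelation(prt, 1000 - 100 * logPr)
  expect_equal(res$byElectrode$r[1], -1, tolerance = 1e-12)
  expect_equal(res$test@alternative, "less")
  # RT independent of PR: |r| small
  set.seed(47)
  resNull <- rtStateCorrelation(prt, rnorm(n, 600, 50))
  expect_lt(abs(resNull$byElectrode$r[1]), 0.4)
  expect_error(rtStateCorrelation(prt, c(rep(NA, n - 5), rnorm(5))),
               "at least 10")
})

test_that("quartile comparison partitions electrodes and detects shifts", {
  set.seed(48)
  ne <- 96
  ssp <- runif(ne, 0.4, 0.9)
  vals <- rnorm(ne, 0, 0.5)
  qc <- quartileComparison(ssp, vals)
  expect_equal(sort(unique(qc$quartile)), 1:4)
  expect_equal(unname(table(qc$quartile)), rep(24L, 4), ignore_attr = TRUE)
  expect_gt(pValue(qc$test), 0.05)
  # a +1 dB shift confined to the first quartile is detected
  shifted <- vals + ifelse(qc$quartile == 1, 1, 0)
  expect_lt(pValue(quartileComparison(ssp, shifted)$test), 0.05)
  expect_error(quartileComparison(ssp[1:6], vals[1:6]), "at least 8")
})
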