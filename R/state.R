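#' Label low/high cortical states by median split
#'
#' Classifies each trial at each electrode as low or high PR according to
#' whether the trial's PR lies below or (strictly) above that electrode's
#' median PR across trials, and likewise labels the population state from
#' the across-electrode mean of the 0-1 normalized PR. Labels are invariant
#' under any monotone transform of PR (they depend on ranks only).
#'
#' @param prTable A [PowerRatioTable-class].
#' @return A [StateLabelTable-class]. Electrodes whose PR is constant across
#'   trials are flagged as degenerate (all labels low) with a warning.
#' @export
labelStates <- function(prTable) {
  stopifnot(is(prTable, "PowerRatioTable"))
  pr <- prTable@pr
  if (nrow(pr) < 2) stop("median split needs at least 2 trials")
  ne <- ncol(pr)
  rng <- apply(pr, 2, range, na.rm = TRUE)
  degenerate <- rng[2, ] - rng[1, ] <= 0
  if (any(degenerate))
    warning("constant PR on electrode(s) ",
            paste(which(degenerate), collapse = ", "),
            ": median split degenerate")
  norm <- pr
  for (e in seq_len(ne)) {
    if (degenerate[e]) {
      norm[, e] <- 0
      next
    }
    norm[, e] <- (pr[, e] - rng[1, e]) / (rng[2, e] - rng[1, e])
  }
  med <- apply(pr, 2, stats::median, na.rm = TRUE)
  labels <- sweep(pr, 2, med, ">")
  labels[is.na(labels)] <- FALSE
  popSeries <- rowMeans(norm)
  popLabel <- popSeries > stats::median(popSeries)
  new("StateLabelTable", labels = labels, populationLabel = popLabel,
      normalizedPr = norm, degenerateElectrodes = degenerate,
      task = prTable@task)
}

#' @rdname corstate-accessors
#' @export
setMethod("stateLabels", "StateLabelTable", function(x, ...) x@labels)

#' @rdname corstate-accessors
#' @export
setMethod("populationLabels", "StateLabelTable", function(x, ...) x@populationLabel)

#' @rdname corstate-accessors
#' @export
setMethod("nTrials", "StateLabelTable", function(x, ...) nrow(x@labels))

#' @rdname corstate-accessors
#' @export
setMethod("nElectrodes", "StateLabelTable", function(x, ...) ncol(x@labels))

#' @describeIn StateLabelTable-class Summary display.
#' @param object A `StateLabelTable`.
#' @export
setMethod("show", "StateLabelTable", function(object) {
  cat(sprintf("StateLabelTable: %d trials x %d electrodes (%d degenerate)\n",
              nrow(object@labels), ncol(object@labels),
              sum(object@degenerateElectrodes)))
  cat(sprintf("  population state: %d high / %d low trials\n",
              sum(object@populationLabel), sum(!object@populationLabel)))
})

# leave-one-out population label: median split of the mean normalized PR of
# the given electrode subset
.population_label <- function(labels, subset) {
  series <- rowMeans(labels@normalizedPr[, subset, drop = FALSE])
  series > stats::median(series)
}

#' Same-state probability of an electrode versus the population
#'
#' Fraction of trials in which an electrode's low/high label matches the
#' label of the rest of the population (median split of the mean normalized
#' PR over `populationSubset`, which excludes the electrode itself), with a
#' trial-shuffle null: permuting the electrode's label sequence destroys the
#' trial-by-trial correspondence, so the shuffled probability is 0.5 in
#' expectation regardless of the degree of state sharing.
#'
#' @param labels A [StateLabelTable-class].
#' @param electrode Electrode index under test.
#' @param populationSubset Electrode indices defining the population;
#'   defaults to all electrodes except `electrode`.
#' @param nPermutations Number of label shuffles for the null (0 to skip).
#' @param seed Integer seed for the shuffles.
#' @return List of class `"sameStateProb"`: `probability`, `null` (vector of
#'   shuffled probabilities), `chanceLevel` (their mean), `pValue`
#'   (smoothed empirical), `electrode`, `n`.
#' @export
sameStateProbability <- function(labels, electrode, populationSubset = NULL,
                                 nPermutations = 1000, seed = 1L) {
  stopifnot(is(labels, "StateLabelTable"))
  ne <- ncol(labels@labels)
  nt <- nrow(labels@labels)
  if (nt < 20) stop("same-state probability needs at least 20 trials")
  if (is.null(populationSubset)) populationSubset <- setdiff(seq_len(ne), electrode)
  if (electrode %in% populationSubset)
    stop("the electrode under test must not belong to the population subset")
  if (!length(populationSubset)) stop("empty population subset")
  el <- labels@labels[, electrode]
  pop <- .population_label(labels, populationSubset)
  prob <- mean(el == pop)
  null <- numeric(0)
  if (nPermutations > 0) {
    null <- .with_seed(seed, vapply(seq_len(nPermutations), function(i) {
      mean(el[sample.int(nt)] == pop)
    }, 0))
  }
  p <- if (length(null)) (1 + sum(null >= prob)) / (length(null) + 1) else NA_real_
  structure(list(probability = prob, null = null,
                 chanceLevel = if (length(null)) mean(null) else NA_real_,
                 pValue = p, electrode = electrode, n = nt),
            class = "sameStateProb")
}

#' @export
print.sameStateProb <- function(x, ...) {
  cat(sprintf("same-state probability, electrode %d: %.3f over %d trials\n",
              x$electrode, x$probability, x$n))
  if (length(x$null))
    cat(sprintf("  shuffle null: %.3f (chance), empirical p = %.4g (%d permutations)\n",
                x$chanceLevel, x$pValue, length(x$null)))
  invisible(x)
}

#' Same-state probability for every electrode
#'
#' Leave-one-out version across the whole array: for each electrode, the
#' population is all remaining electrodes.
#'
#' @param labels A [StateLabelTable-class].
#' @return Numeric vector, one probability per electrode.
#' @export
sameStateProbabilities <- function(labels) {
  stopifnot(is(labels, "StateLabelTable"))
  ne <- ncol(labels@labels)
  vapply(seq_len(ne), function(e) {
    pop <- .population_label(labels, setdiff(seq_len(ne), e))
    mean(labels@labels[, e] == pop)
  }, 0)
}

#' Perceptual performance by state bin
#'
#' Percent correct per cortical-state bin: a median split of the population
#' state (`nBins = 2`) or equal-width bins over the range of the population
#' PR series (`nBins = 3` for the tertile analysis). The difference between
#' the extreme bins is tested by bootstrap resampling of trials within bins.
#'
#' @param labels A [StateLabelTable-class].
#' @param outcome Character per trial, `"correct"`/`"incorrect"`.
#' @param nBins 2 (median split) or more (equal-width bins).
#' @param nIterations Bootstrap iterations.
#' @param seed Integer seed.
#' @return List of class `"statePerformance"`: `byBin` data.frame (bin, n,
#'   percentCorrect), `difference` (last minus first bin, percentage
#'   points), `bootstrap` (a `"bootstrapDiff"`), `emptyBins`.
#' @export
performanceByState <- function(labels, outcome, nBins = 2,
                               nIterations = 10000, seed = 1L) {
  stopifnot(is(labels, "StateLabelTable"),
            length(outcome) == nrow(labels@labels), nBins >= 2)
  y <- as.integer(outcome == "correct")
  if (nBins == 2) {
    bin <- as.integer(labels@populationLabel) + 1L
  } else {
    series <- rowMeans(labels@normalizedPr)
    br <- seq(min(series), max(series), length.out = nBins + 1)
    bin <- findInterval(series, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  counts <- tabulate(bin, nBins)
  empty <- which(counts == 0)
  if (length(empty))
    warning("empty state bin(s): ", paste(empty, collapse = ", "),
            "; bins are reported as-is, not merged")
  perf <- vapply(seq_len(nBins), function(b) {
    if (counts[b] == 0) NA_real_ else 100 * mean(y[bin == b])
  }, 0)
  bs <- NULL
  diffPct <- NA_real_
  if (counts[1] > 0 && counts[nBins] > 0) {
    bs <- bootstrapDiff(y[bin == nBins], y[bin == 1],
                        nIterations = nIterations, seed = seed)
    diffPct <- perf[nBins] - perf[1]
  }
  structure(list(byBin = data.frame(bin = seq_len(nBins), n = counts,
                                    percentCorrect = perf),
                 difference = diffPct, bootstrap = bs, emptyBins = empty),
            class = "statePerformance")
}

#' @export
print.statePerformance <- function(x, ...) {
  nb <- nrow(x$byBin)
  lab <- if (nb == 2) c("low PR", "high PR") else paste("bin", seq_len(nb))
  for (b in seq_len(nb))
    cat(sprintf("  %s: %.2f%% correct (n = %d)\n", lab[b],
                x$byBin$percentCorrect[b], x$byBin$n[b]))
  if (!is.null(x$bootstrap))
    cat(sprintf("  difference (top - bottom): %+.2f points, bootstrap p = %.4g\n",
                x$difference, x$bootstrap$p))
  invisible(x)
}

#' Correct-versus-incorrect power-ratio contrast
#'
#' For each electrode, the percentage difference of the mean PR between
#' correct and incorrect trials, `100 * (mean PR_correct - mean PR_incorrect)
#' / mean PR_incorrect`, together with the difference of mean log PR (on
#' which the population tests run: a two-sided Wilcoxon signed rank across
#' electrodes, and a one-sided signed rank for a positive or negative median
#' percentage difference).
#'
#' @param prTable A [PowerRatioTable-class].
#' @param outcome Character per trial.
#' @param direction Direction of the one-sided population test:
#'   `"auto"` (sign of the median percent difference), `"positive"` or
#'   `"negative"`.
#' @return List of class `"prContrast"`: `byElectrode` data.frame,
#'   `twoSided` and `oneSided` [TestResult-class]s, `skipped` electrodes
#'   (missing a condition).
#' @export
prOutcomeContrast <- function(prTable, outcome,
                              direction = c("auto", "positive", "negative")) {
  stopifnot(is(prTable, "PowerRatioTable"),
            length(outcome) == nrow(prTable@pr))
  direction <- match.arg(direction)
  cor_i <- outcome == "correct"
  ne <- ncol(prTable@pr)
  skipped <- integer(0)
  res <- data.frame(electrode = seq_len(ne), nCorrect = NA_integer_,
                    nIncorrect = NA_integer_, meanPrCorrect = NA_real_,
                    meanPrIncorrect = NA_real_, pctDiff = NA_real_,
                    logDiff = NA_real_)
  for (e in seq_len(ne)) {
    ok <- !prTable@flagged[, e]
    nc <- sum(ok & cor_i); ni <- sum(ok & !cor_i)
    res$nCorrect[e] <- nc; res$nIncorrect[e] <- ni
    if (nc < 1 || ni < 1) {
      skipped <- c(skipped, e)
      next
    }
    mc <- mean(prTable@pr[ok & cor_i, e])
    mi <- mean(prTable@pr[ok & !cor_i, e])
    res$meanPrCorrect[e] <- mc
    res$meanPrIncorrect[e] <- mi
    res$pctDiff[e] <- 100 * (mc - mi) / mi
    res$logDiff[e] <- mean(prTable@logPr[ok & cor_i, e]) -
      mean(prTable@logPr[ok & !cor_i, e])
  }
  if (length(skipped) == ne) stop("no electrode has both outcome conditions")
  use <- setdiff(seq_len(ne), skipped)
  alt <- switch(direction,
                auto = if (stats::median(res$pctDiff[use]) >= 0) "greater" else "less",
                positive = "greater", negative = "less")
  structure(list(byElectrode = res,
                 twoSided = wilcoxonSignedRank(res$logDiff[use]),
                 oneSided = wilcoxonSignedRank(res$pctDiff[use],
                                               alternative = alt),
                 skipped = skipped),
            class = "prContrast")
}

#' @export
print.prContrast <- function(x, ...) {
  use <- setdiff(seq_len(nrow(x$byElectrode)), x$skipped)
  pd <- x$byElectrode$pctDiff[use]
  cat(sprintf(
    "PR contrast (correct vs incorrect): %+.2f%% +- %.2f%% (mean +- SEM, n = %d electrodes)\n",
    mean(pd), stats::sd(pd) / sqrt(length(pd)), length(pd)))
  cat("  two-sided (log PR): p =", format(x$twoSided@pValue, digits = 4), "\n")
  cat(sprintf("  one-sided (%s median %% difference): p = %s\n",
              x$oneSided@alternative, format(x$oneSided@pValue, digits = 4)))
  invisible(x)
}

#' Evoked-response analysis
#'
#' Measures the broad-band evoked power in the stimulus windows (dB relative
#' to each electrode's session-wide mean pre-stimulus broad-band power),
#' correlates it with the pre-stimulus state, and, for discrimination
#' trials, contrasts the test-minus-target difference between low- and
#' high-state trials (population median split): a larger difference in the
#' low-PR (desynchronized) state indicates better separability of the two
#' successive stimuli.
#'
#' @param session An [EcogSession-class].
#' @param prTable The matching [PowerRatioTable-class].
#' @param labels Optional [StateLabelTable-class] (computed from `prTable`
#'   when missing) used for the low/high split.
#' @return List of class `"evokedAnalysis"`: `evoked` ([EvokedTable-class]),
#'   `correlation` data.frame (per-electrode Pearson r between log PR and
#'   target evoked dB), `rTest` (one-sided signed rank for a positive median
#'   r), and for discrimination trials `stateSplit` (per-electrode mean
#'   test-minus-target dB in low/high states, group means, and a two-sided
#'   signed-rank comparison).
#' @export
evokedAnalysis <- function(session, prTable, labels = NULL) {
  stopifnot(is(session, "EcogSession"), is(prTable, "PowerRatioTable"),
            nTrials(session) == nrow(prTable@pr))
  if (is.null(labels)) labels <- suppressWarnings(labelStates(prTable))
  mk <- session@markers
  fs <- session@fs
  nt <- nTrials(session)
  ne <- nElectrodes(session)
  preIdx <- (mk[["stim1On"]] - as.integer(round(0.4 * fs))):(mk[["stim1On"]] - 1L)
  s1 <- mk[["stim1On"]]:mk[["stim1Off"]]
  s2 <- mk[["stim2On"]]:mk[["stim2Off"]]
  disc <- session@task == "discrimination"
  targetDb <- matrix(NA_real_, nt, ne)
  testDb <- matrix(NA_real_, nt, ne)
  ref <- numeric(ne)
  for (e in seq_len(ne)) {
    x <- matrix(session@voltages[, e, ], nrow = nt)     # trials x samples
    ref[e] <- mean(x[, preIdx]^2)
    targetDb[, e] <- 10 * log10(rowMeans(x[, s1, drop = FALSE]^2) / ref[e])
    if (any(disc))
      testDb[disc, e] <- 10 * log10(rowMeans(x[disc, s2, drop = FALSE]^2) / ref[e])
  }
  evoked <- new("EvokedTable", targetDb = targetDb, testDb = testDb,
                diffDb = testDb - targetDb, referencePower = ref,
                task = session@task)
  r <- vapply(seq_len(ne), function(e) {
    ok <- !prTable@flagged[, e]
    stats::cor(prTable@logPr[ok, e], targetDb[ok, e])
  }, 0)
  out <- list(evoked = evoked,
              correlation = data.frame(electrode = seq_len(ne), r = r),
              rTest = wilcoxonSignedRank(r, alternative = "greater"),
              stateSplit = NULL)
  if (sum(disc) >= 4) {
    lowT <- disc & !labels@populationLabel
    highT <- disc & labels@populationLabel
    if (sum(lowT) >= 2 && sum(highT) >= 2) {
      lowMean <- colMeans(evoked@diffDb[lowT, , drop = FALSE])
      highMean <- colMeans(evoked@diffDb[highT, , drop = FALSE])
      out$stateSplit <- list(
        byElectrode = data.frame(electrode = seq_len(ne), low = lowMean,
                                 high = highMean),
        lowDb = mean(lowMean), highDb = mean(highMean),
        test = wilcoxonSignedRank(lowMean, highMean))
    }
  }
  structure(out, class = "evokedAnalysis")
}

#' @export
print.evokedAnalysis <- function(x, ...) {
  r <- x$correlation$r
  cat(sprintf(
    "evoked response vs state: Pearson r = %.3f +- %.3f (mean +- SEM, n = %d electrodes), one-sided p = %s\n",
    mean(r), stats::sd(r) / sqrt(length(r)), length(r),
    format(x$rTest@pValue, digits = 4)))
  if (!is.null(x$stateSplit))
    cat(sprintf(
      "  test - target: %+.3f dB (low PR) vs %+.3f dB (high PR), two-sided p = %s\n",
      x$stateSplit$lowDb, x$stateSplit$highDb,
      format(x$stateSplit$test@pValue, digits = 4)))
  invisible(x)
}

#' Reaction-time versus state correlation
#'
#' Per-electrode Pearson correlation between log PR and reaction time over
#' correct (responded) trials, with a one-sided population signed-rank test.
#' A negative correlation means faster responses in the synchronized state.
#'
#' @param prTable A [PowerRatioTable-class].
#' @param reactionTime Numeric per trial (ms), `NA` where no response.
#' @param direction One-sided direction: `"auto"` (sign of the median r),
#'   `"negative"` or `"positive"`.
#' @return List of class `"rtCorrelation"`: `byElectrode` data.frame, `test`
#'   ([TestResult-class]), `n` correct trials used.
#' @export
rtStateCorrelation <- function(prTable, reactionTime,
                               direction = c("auto", "negative", "positive")) {
  stopifnot(is(prTable, "PowerRatioTable"),
            length(reactionTime) == nrow(prTable@pr))
  direction <- match.arg(direction)
  ok <- !is.na(reactionTime)
  if (sum(ok) < 10) stop("need at least 10 responded trials")
  r <- vapply(seq_len(ncol(prTable@pr)), function(e) {
    use <- ok & !prTable@flagged[, e]
    stats::cor(prTable@logPr[use, e], reactionTime[use])
  }, 0)
  alt <- switch(direction,
                auto = if (stats::median(r) >= 0) "greater" else "less",
                positive = "greater", negative = "less")
  structure(list(byElectrode = data.frame(electrode = seq_along(r), r = r),
                 test = wilcoxonSignedRank(r, alternative = alt),
                 n = sum(ok)),
            class = "rtCorrelation")
}

#' @export
print.rtCorrelation <- function(x, ...) {
  cat(sprintf(
    "reaction time vs state: median r = %.3f over %d electrodes (%d trials), one-sided (%s) p = %s\n",
    stats::median(x$byElectrode$r), nrow(x$byElectrode), x$n,
    x$test@alternative, format(x$test@pValue, digits = 4)))
  invisible(x)
}

#' Quartile comparison of state-correlated electrodes
#'
#' Splits electrodes into quartiles of their same-state probability (stable
#' rank order resolves ties) and compares a per-electrode quantity (e.g.
#' mean evoked response) between the first and fourth quartiles with a
#' two-sided Wilcoxon rank-sum test (the groups are disjoint electrodes, so
#' the comparison is unpaired).
#'
#' @param sameStateProbs Numeric per electrode (see
#'   [sameStateProbabilities()]).
#' @param values Numeric per electrode to compare.
#' @return List of class `"quartileComparison"`: `quartile` membership per
#'   electrode, group means of `values` for Q1 and Q4, `test`
#'   ([TestResult-class]).
#' @export
quartileComparison <- function(sameStateProbs, values) {
  ne <- length(sameStateProbs)
  stopifnot(length(values) == ne)
  if (ne < 8) stop("quartile comparison needs at least 8 electrodes")
  rk <- rank(sameStateProbs, ties.method = "first")
  quartile <- as.integer(cut(rk, breaks = stats::quantile(rk, 0:4 / 4),
                             include.lowest = TRUE, labels = FALSE))
  q1 <- values[quartile == 1]
  q4 <- values[quartile == 4]
  structure(list(quartile = quartile,
                 meanQ1 = mean(q1), meanQ4 = mean(q4),
                 test = wilcoxonRankSum(q1, q4)),
            class = "quartileComparison")
}

#' @export
print.quartileComparison <- function(x, ...) {
  cat(sprintf(
    "quartile comparison (same-state probability): Q1 mean %.3f vs Q4 mean %.3f, two-sided p = %s\n",
    x$meanQ1, x$meanQ4, format(x$test@pValue, digits = 4)))
  invisible(x)
}
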