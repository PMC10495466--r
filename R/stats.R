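# Rank tests wrap stats::wilcox.test so that sidedness, pairing and the
# exact/asymptotic crossover are explicit and uniformly reported.

.test_result <- function(statistic, p, alternative, method, n,
                         correction = "none", familySize = 1L) {
  new("TestResult", statistic = unname(statistic), pValue = unname(p),
      alternative = alternative, method = method, n = as.integer(n),
      correction = correction, familySize = as.integer(familySize))
}

#' @rdname corstate-accessors
#' @export
setMethod("pValue", "TestResult", function(x, ...) x@pValue)

#' @describeIn TestResult-class Compact display.
#' @param object A `TestResult`.
#' @export
setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s test (%s, n = %s): statistic = %g, p = %g",
              object@method, object@alternative,
              paste(object@n, collapse = "/"), object@statistic,
              object@pValue))
  if (object@correction != "none")
    cat(sprintf(" [%s, family %d]", object@correction, object@familySize))
  cat("\n")
})

#' Wilcoxon signed-rank test
#'
#' One-sample (or paired) signed-rank test with explicit sidedness:
#' `alternative = "greater"` is the one-sided test for a positive median.
#' The null distribution is exact for fewer than `exactLimit` observations
#' without ties or zeros, and a normal approximation with continuity
#' correction otherwise.
#'
#' @param x Numeric vector (differences, or first sample).
#' @param y Optional second sample for a paired test.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exactLimit Sample-size crossover to the asymptotic null.
#' @return A [TestResult-class].
#' @examples
#' wilcoxonSignedRank(c(2, 1, 4, 3, 6, 5, 8, 7) - 2, alternative = "greater")
#' @export
wilcoxonSignedRank <- function(x, y = NULL,
                               alternative = c("two.sided", "greater", "less"),
                               exactLimit = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0))
    stop("signed-rank test undefined: all differences are zero")
  exact <- length(d) < exactLimit && !any(d == 0) && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = TRUE))
  .test_result(ht$statistic, ht$p.value, alternative,
               "wilcoxon-signed-rank", length(d))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank test with explicit sidedness; exact null when the smaller
#' sample has at most `exactLimit` observations and there are no ties,
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exactLimit Small-sample crossover for the exact null.
#' @return A [TestResult-class].
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "greater", "less"),
                            exactLimit = 10) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- min(length(x), length(y)) <= exactLimit &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  .test_result(ht$statistic, ht$p.value, alternative, "wilcoxon-rank-sum",
               c(length(x), length(y)))
}

#' Bonferroni correction
#'
#' Elementwise `min(1, p * familySize)`.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param familySize Number of tests in the family; defaults to
#'   `length(pvals)`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(pvals, familySize = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), familySize >= 1)
  pmin(1, pvals * familySize)
}

#' Bootstrap comparison of two groups
#'
#' Resamples each group with replacement, recomputes the statistic
#' difference (`x` minus `y`), and reports the smoothed empirical two-sided
#' p-value `2 * min(#(D <= 0) + 1, #(D >= 0) + 1) / (B + 1)` (capped at 1)
#' together with a percentile confidence interval. When both groups are
#' binary and the statistic is the mean, resampling is done in closed form
#' through binomial draws, which makes millions of iterations cheap.
#'
#' @param x,y Numeric vectors.
#' @param statistic Function of a vector; mean by default.
#' @param nIterations Bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return List of class `"bootstrapDiff"`: observed difference, `p`, `ci`,
#'   `nIterations`, and a degeneracy flag when the resampled differences are
#'   constant.
#' @export
bootstrapDiff <- function(x, y, statistic = mean, nIterations = 10000,
                          seed = 1L, conf = 0.95) {
  stopifnot(length(x) > 0, length(y) > 0)
  obs <- statistic(x) - statistic(y)
  .with_seed(seed, {
    binary <- all(x %in% c(0, 1)) && all(y %in% c(0, 1)) &&
      identical(statistic, mean)
    d <- if (binary) {
      stats::rbinom(nIterations, length(x), mean(x)) / length(x) -
        stats::rbinom(nIterations, length(y), mean(y)) / length(y)
    } else {
      vapply(seq_len(nIterations), function(i) {
        statistic(x[sample.int(length(x), replace = TRUE)]) -
          statistic(y[sample.int(length(y), replace = TRUE)])
      }, 0)
    }
    degenerate <- stats::sd(d) == 0
    p <- min(1, 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (nIterations + 1))
    ci <- stats::quantile(d, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    if (degenerate)
      warning("bootstrap distribution is degenerate (zero variance)")
    structure(list(observed = obs, p = p, ci = ci,
                   nIterations = nIterations, degenerate = degenerate),
              class = "bootstrapDiff")
  })
}

#' @export
print.bootstrapDiff <- function(x, ...) {
  cat(sprintf("bootstrap difference: %.4g (CI [%.4g, %.4g]), p = %.4g (%d iterations)\n",
              x$observed, x$ci[1], x$ci[2], x$p, x$nIterations))
  invisible(x)
}
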