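# Fisher linear discriminant: direction maximizing between- over within-
# class scatter, threshold at the midpoint of the projected class means.
# The within-class scatter is ridge-regularized only when ill-conditioned.
.flda_train <- function(x, y, ridge = 1e-3) {
  x0 <- x[!y, , drop = FALSE]
  x1 <- x[y, , drop = FALSE]
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  S <- crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))
  d <- ncol(x)
  regularized <- FALSE
  w <- NULL
  if (rcond(S) > 1e-10)
    w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w)) {
    regularized <- TRUE
    lam <- ridge * sum(diag(S)) / d
    if (lam <= 0) lam <- ridge
    w <- solve(S + diag(lam, d), m1 - m0)
  }
  list(w = w, threshold = sum(w * (m0 + m1)) / 2, regularized = regularized)
}

# stratified fold assignment: per class, folds are dealt out as evenly as
# possible, so per-fold class proportions differ from global by <= 1 trial
.stratified_folds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in c(FALSE, TRUE)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

#' Cross-validated Fisher linear discriminant
#'
#' Stratified k-fold cross-validation of a Fisher LDA predicting a binary
#' trial label (correct versus incorrect) from a feature vector per trial
#' (typically the per-electrode pre-stimulus log PR). The discriminant
#' direction maximizes the ratio of between- to within-class scatter; the
#' decision threshold is the midpoint of the projected class means (equal
#' priors, as used with balanced class draws). A singular within-class
#' scatter is ridge-regularized (`lambda = ridge * trace / dim`) and
#' reported via the `regularizedFolds` attribute.
#'
#' @param features Numeric matrix, trials x features (a vector is treated as
#'   a single feature).
#' @param labels Logical or `"correct"`/`"incorrect"` per trial; `TRUE`
#'   (correct) is the positive class.
#' @param nFolds Number of folds.
#' @param ridge Regularization scale applied when the scatter matrix is
#'   ill-conditioned.
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of per-fold accuracies, with attribute
#'   `regularizedFolds`.
#' @examples
#' x <- matrix(c(rnorm(30), rnorm(30) + 3))
#' y <- rep(c(FALSE, TRUE), each = 30)
#' mean(fldaFitPredict(x, y, seed = 2))   # separable: accuracy 1
#' @export
fldaFitPredict <- function(features, labels, nFolds = 5, ridge = 1e-3,
                           seed = NULL) {
  x <- as.matrix(features)
  y <- if (is.logical(labels)) labels else labels == "correct"
  stopifnot(nrow(x) == length(y))
  if (min(sum(y), sum(!y)) < 2 * nFolds)
    stop("each class needs at least 2 trials per fold")
  run <- function() {
    fold <- .stratified_folds(y, nFolds)
    acc <- numeric(nFolds)
    nreg <- 0L
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      fit <- .flda_train(x[tr, , drop = FALSE], y[tr], ridge)
      pred <- drop(x[!tr, , drop = FALSE] %*% fit$w) > fit$threshold
      acc[f] <- mean(pred == y[!tr])
      if (fit$regularized) nreg <- nreg + 1L
    }
    structure(acc, regularizedFolds = nreg)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Decode trial outcome from the pre-stimulus state
#'
#' Balanced-subsampling decoder: in each iteration, equal numbers of correct
#' and incorrect trials are drawn (without replacement, `min` of the class
#' counts per class), a Fisher LDA is cross-validated with stratified
#' 5-fold, and the mean fold accuracy is recorded. The empirical p-value is
#' the fraction of iterations with accuracy below the 0.5 chance level.
#'
#' @param features A [PowerRatioTable-class] (its log-PR matrix is the
#'   feature set) or a trials x features numeric matrix.
#' @param outcome Character per trial, `"correct"`/`"incorrect"`.
#' @param nIterations Number of balanced subsampling iterations.
#' @param seed Integer seed; the result is reproducible given `seed`.
#' @param nFolds Cross-validation folds.
#' @param mode `"population"` (default) uses the across-electrode mean log PR
#'   as a single feature -- the trial's cortical state; `"vector"` uses the
#'   per-electrode feature vector. With tens of electrodes and of the order
#'   of a hundred trials the vector mode overfits badly and its
#'   cross-validated accuracy drops below the single-feature mode (see the
#'   methods vignette).
#' @return A [DecoderResult-class].
#' @export
decodeOutcome <- function(features, outcome, nIterations = 1000, seed = 1L,
                          nFolds = 5, mode = c("population", "vector")) {
  mode <- match.arg(mode)
  x <- if (is(features, "PowerRatioTable")) features@logPr else as.matrix(features)
  if (mode == "population") x <- matrix(rowMeans(x), ncol = 1)
  y <- outcome == "correct"
  stopifnot(nrow(x) == length(y))
  nPer <- min(sum(y), sum(!y))
  if (nPer < 10)
    stop("decoder aborted: fewer than 10 trials in the minority class")
  idx0 <- which(!y)
  idx1 <- which(y)
  .with_seed(seed, {
    acc <- vapply(seq_len(nIterations), function(i) {
      take <- c(sample(idx0, nPer), sample(idx1, nPer))
      mean(fldaFitPredict(x[take, , drop = FALSE], y[take], nFolds = nFolds))
    }, 0)
    new("DecoderResult", accuracies = acc,
        nIterations = as.integer(nIterations),
        subsampleSize = as.integer(nPer), nFeatures = ncol(x),
        pValue = mean(acc < 0.5), seed = as.integer(seed))
  })
}

#' @rdname corstate-accessors
#' @export
setMethod("accuracies", "DecoderResult", function(x, ...) x@accuracies)

#' @rdname corstate-accessors
#' @export
setMethod("pValue", "DecoderResult", function(x, ...) x@pValue)

#' @describeIn DecoderResult-class Summary display.
#' @param object A `DecoderResult`.
#' @export
setMethod("show", "DecoderResult", function(object) {
  cat(sprintf(
    "DecoderResult: accuracy %.4f +- %.4f (mean +- sd over %d iterations)\n",
    mean(object@accuracies), stats::sd(object@accuracies),
    object@nIterations))
  cat(sprintf("  %d features, %d trials/class per draw, p = %.4g (fraction below 0.5)\n",
              object@nFeatures, object@subsampleSize, object@pValue))
})
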