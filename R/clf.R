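## Binary decoding of direction pairs: L2-regularized logistic regression
## inside a stratified 10-fold outer / 5-fold inner nested cross-validation.
## Per outer fold the features are z-normalized with statistics from that
## fold's training set only; the inner grid search picks the smallest
## regularization strength among the accuracy maximizers; significance is
## assessed with a McNemar test against the majority-class assignment.

#' Default regularization grid
#'
#' Logarithmic grid of 13 L2 strengths from 1e-3 to 1e3.
#'
#' @return numeric vector, ascending.
#' @export
defaultLambdaGrid <- function() 10^seq(-3, 3, by = 0.5)

#' Fit an L2-regularized logistic regression
#'
#' Minimizes mean negative log-likelihood + (lambda/2) * ||w||^2 (intercept
#' unpenalized) by damped Newton iterations, stopping when the infinity norm
#' of the gradient falls below \code{tol} or after \code{maxit} iterations.
#'
#' @param X numeric matrix, observations x features.
#' @param y binary labels: logical, 0/1, factor, or any two distinct values.
#' @param lambda L2 regularization strength (>= 0).
#' @param tol gradient infinity-norm convergence tolerance (default 1e-7).
#' @param maxit maximum Newton iterations (default 1000).
#' @return a \linkS4class{LogRegModel}. The positive class is the second of
#'   \code{sort(unique(y))}.
#' @examples
#' X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
#' fitLogregL2(X, c(0, 0, 1, 1), lambda = 0.01)
#' @export
fitLogregL2 <- function(X, y, lambda, tol = 1e-7, maxit = 1000) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in the feature matrix")
  lev <- sort(unique(y))
  if (length(lev) != 2)
    stop("y must contain exactly two classes (got ", length(lev), ")")
  y01 <- as.numeric(y == lev[2])
  fit <- .lrFitCpp(X, y01, lambda, tol, maxit)
  new("LogRegModel", w = as.numeric(fit$w), b = fit$b, lambda = lambda,
      converged = fit$converged, gradNorm = fit$gradNorm,
      iterations = fit$iterations)
}

#' Decision values / probabilities of a fitted model
#'
#' @param object a \linkS4class{LogRegModel}.
#' @param X feature matrix.
#' @param type \code{"prob"} for P(positive class), \code{"score"} for the
#'   linear decision value, \code{"class"} for 0/1 labels.
#' @return numeric vector.
#' @export
predictLogreg <- function(object, X, type = c("class", "prob", "score")) {
  type <- match.arg(type)
  z <- as.numeric(as.matrix(X) %*% object@w + object@b)
  switch(type, score = z, prob = stats::plogis(z),
         class = as.numeric(z > 0))
}

## stratified fold assignment: shuffle within class, deal folds round-robin
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' McNemar test of a classifier against the majority-class assignment
#'
#' The majority predictor assigns every trial to the larger class (ties go to
#' \code{tieClass}). With b = trials the classifier gets right and the
#' majority predictor wrong, and c the reverse, the test is an exact
#' two-sided binomial test of b against b + c when b + c < 25, and otherwise
#' the continuity-corrected chi-squared statistic (|b - c| - 1)^2 / (b + c).
#'
#' @param predicted predicted labels.
#' @param actual true labels.
#' @param tieClass label the majority predictor uses when classes tie
#'   (default: the first of \code{sort(unique(actual))}).
#' @return list with \code{p} (two-sided), \code{b}, \code{c},
#'   \code{majorityClass} and \code{degenerate} (TRUE when b + c = 0, where
#'   p = 1 by convention).
#' @examples
#' mcnemarVsMajority(rep(1, 30), rep(c(1, 2), 15))$p   # classifier = majority
#' @export
mcnemarVsMajority <- function(predicted, actual, tieClass = NULL) {
  tab <- table(actual)
  if (is.null(tieClass)) tieClass <- sort(unique(actual))[1]
  mx <- max(tab)
  winners <- names(tab)[tab == mx]
  majClass <- if (length(winners) > 1) as.character(tieClass) else winners
  majCorrect <- as.character(actual) == majClass
  clfCorrect <- predicted == actual
  b <- sum(clfCorrect & !majCorrect)
  cc <- sum(!clfCorrect & majCorrect)
  if (b + cc == 0)
    return(list(p = 1, b = b, c = cc, majorityClass = majClass,
                degenerate = TRUE))
  p <- if (b + cc < 25) {
    min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p = p, b = b, c = cc, majorityClass = majClass, degenerate = FALSE)
}

#' Nested cross-validation for one direction pair
#'
#' Stratified outer k-fold cross-validation; within each outer training set,
#' features are z-normalized (the statistics are then applied to the outer
#' test fold), an inner stratified grid search picks the regularization
#' strength — the smallest value among the accuracy maximizers — and the
#' classifier is retrained on the full outer training set. The reported
#' accuracy is the pooled fraction of correct predictions over all outer
#' test folds.
#'
#' @param x a \linkS4class{FeatureMatrix} restricted to two directions, or a
#'   plain feature matrix (then \code{y} is required).
#' @param y labels when \code{x} is a matrix; ignored otherwise.
#' @param lambdaGrid candidate L2 strengths (default [defaultLambdaGrid()]).
#' @param outerFolds,innerFolds fold counts (defaults 10 and 5).
#' @param seed integer seed controlling all fold assignments.
#' @return a \linkS4class{PairCVResult}.
#' @export
nestedCV <- function(x, y = NULL, lambdaGrid = defaultLambdaGrid(),
                     outerFolds = 10, innerFolds = 5, seed = 1L) {
  if (methods::is(x, "FeatureMatrix")) {
    y <- x@direction
    ids <- x@trialId
    X <- x@X
  } else {
    if (is.null(y)) stop("y is required when x is a plain matrix")
    X <- as.matrix(x)
    ids <- seq_len(nrow(X))
  }
  if (length(lambdaGrid) == 0) stop("lambdaGrid must not be empty")
  lambdaGrid <- sort(as.numeric(lambdaGrid))
  pair <- sort(unique(y))
  if (length(pair) != 2)
    stop("nested CV requires exactly two classes (got ", length(pair), ")")
  cnt <- table(y)
  if (min(cnt) < outerFolds)
    stop("each class needs at least ", outerFolds, " trials; got ",
         paste(sprintf("%s: %d", names(cnt), as.integer(cnt)),
               collapse = ", "))
  y01 <- as.numeric(y == pair[2])
  n <- nrow(X)

  .withSeed(seed, {
    outerId <- .stratifiedFolds(y01, outerFolds)
    predicted01 <- numeric(n)
    lambdaPerFold <- numeric(outerFolds)
    for (f in seq_len(outerFolds)) {
      tr <- which(outerId != f)
      te <- which(outerId == f)
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd[sd == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd, "/")
      innerId <- .stratifiedFolds(y01[tr], innerFolds)
      acc <- .lrCvAccCpp(Xtr, y01[tr], as.integer(innerId), lambdaGrid)
      ## ascending grid: first maximizer = smallest lambda among the best
      lam <- lambdaGrid[which.max(acc)]
      lambdaPerFold[f] <- lam
      fit <- .lrFitCpp(Xtr, y01[tr], lam, 1e-7, 1000)
      predicted01[te] <- as.numeric(Xte %*% fit$w + fit$b > 0)
    }
    predLab <- pair[predicted01 + 1]
    actLab <- pair[y01 + 1]
    mc <- mcnemarVsMajority(predLab, actLab, tieClass = pair[1])
    new("PairCVResult", pair = as.integer(pair),
        predictions = data.frame(trial_id = ids, fold = outerId,
                                 actual = actLab, predicted = predLab),
        accuracy = mean(predLab == actLab),
        lambdaPerFold = lambdaPerFold, mcnemarP = mc$p,
        nTrials = as.integer(n), degenerate = mc$degenerate)
  })
}

#' Classify all fifteen direction pairs
#'
#' Runs the Welch-feature nested-CV classifier for every unordered pair of
#' the six cued directions and reports per-pair accuracies, McNemar p-values,
#' significance flags at 0.05 and 0.001, and the subject's peak accuracy and
#' best pair.
#'
#' @param epochs an \linkS4class{EpochSet} after CSD filtering, with a linked
#'   trial table containing all six directions.
#' @param electrodes electrode subset (default [posteriorElectrodes()]).
#' @param lambdaGrid,outerFolds,innerFolds see [nestedCV()].
#' @param windowMs,bandHz,nSegments,overlap see [welchBandpower()].
#' @param minTrials minimum trials per direction and pair (default 10).
#' @param seed integer seed; pair k uses child seed \code{seed + k}.
#' @return list with \code{results} (15 \linkS4class{PairCVResult}),
#'   \code{summary} (data.frame: pair_a, pair_b, accuracy, p, sig05, sig001),
#'   \code{peakAccuracy} and \code{bestPair}.
#' @export
allPairsAnalysis <- function(epochs, electrodes = posteriorElectrodes(),
                             lambdaGrid = defaultLambdaGrid(),
                             outerFolds = 10, innerFolds = 5,
                             windowMs = c(500, 2000), bandHz = c(8, 12),
                             nSegments = 8, overlap = 0.5, minTrials = 10,
                             seed = 1L) {
  dirs <- sort(unique(epochs@trials$direction))
  if (!identical(as.integer(dirs), 1:6))
    stop("all six directions must be present; found: ",
         paste(dirs, collapse = ", "))
  fm <- welchBandpower(selectChannels(epochs, electrodes), windowMs, bandHz,
                       nSegments, overlap)
  pairs <- utils::combn(1:6, 2)
  results <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    pfm <- featurePair(fm, pairs[, k], minTrials)
    results[[k]] <- nestedCV(pfm, lambdaGrid = lambdaGrid,
                             outerFolds = outerFolds,
                             innerFolds = innerFolds, seed = seed + k)
  }
  summary <- data.frame(
    pair_a = pairs[1, ], pair_b = pairs[2, ],
    accuracy = vapply(results, function(r) r@accuracy, 0),
    p = vapply(results, function(r) r@mcnemarP, 0))
  summary$sig05 <- summary$p < 0.05
  summary$sig001 <- summary$p < 0.001
  best <- which.max(summary$accuracy)
  list(results = results, summary = summary,
       peakAccuracy = summary$accuracy[best],
       bestPair = c(pairs[1, best], pairs[2, best]))
}
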