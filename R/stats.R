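## Ancillary analyses: behavioral statistics, signed r^2 topography of
## left- vs right-directed shifts, hemisphere-subset comparison (one-way
## ANOVA + Tukey-Kramer), and the EOG confound classification.

#' Behavioral statistics across subjects
#'
#' Computes per-subject response accuracy and geometric-mean reaction times
#' (exponential of the mean log RT) in the valid and invalid cue conditions,
#' and paired-samples t-tests across subjects on accuracy and on log
#' geometric-mean RT (valid vs invalid). Validly cued targets should be
#' answered faster; accuracy is expected not to differ.
#'
#' @param trialTables list of per-subject trial tables with responses filled
#'   (see [generateBehavior()]).
#' @param latencyFilter restrict to trials with this target latency in ms
#'   (NULL = all trials).
#' @return list with \code{perSubject} (data.frame), \code{accuracyTest} and
#'   \code{rtTest} (each \code{list(t, df, p)}; NA with fewer than 2
#'   subjects), and cohort means.
#' @export
behavioralStats <- function(trialTables, latencyFilter = NULL) {
  if (!is.list(trialTables) || !length(trialTables))
    stop("trialTables must be a non-empty list of trial tables")
  per <- lapply(seq_along(trialTables), function(i) {
    tt <- trialTables[[i]]
    if (!is.null(latencyFilter))
      tt <- tt[tt$target_latency_ms == latencyFilter, , drop = FALSE]
    if (any(!is.na(tt$rt_ms) & tt$rt_ms <= 0))
      stop("non-positive reaction times in subject ", i)
    geo <- function(x) exp(mean(log(x)))
    data.frame(
      subject = i,
      accuracy = mean(tt$correct),
      accuracy_valid = mean(tt$correct[tt$valid]),
      accuracy_invalid = mean(tt$correct[!tt$valid]),
      rt_geo_valid = geo(tt$rt_ms[tt$valid]),
      rt_geo_invalid = geo(tt$rt_ms[!tt$valid]))
  })
  per <- do.call(rbind, per)
  pairedT <- function(a, b) {
    if (nrow(per) < 2 || isTRUE(all.equal(a, b)))
      return(list(t = if (isTRUE(all.equal(a, b))) 0 else NA_real_,
                  df = nrow(per) - 1,
                  p = if (isTRUE(all.equal(a, b))) 1 else NA_real_))
    tt <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }
  list(perSubject = per,
       accuracyTest = pairedT(per$accuracy_valid, per$accuracy_invalid),
       rtTest = pairedT(log(per$rt_geo_invalid), log(per$rt_geo_valid)),
       meanAccuracy = mean(per$accuracy),
       meanGeoValid = mean(per$rt_geo_valid),
       meanGeoInvalid = mean(per$rt_geo_invalid))
}

#' Signed squared point-biserial correlation per electrode
#'
#' For each electrode, computes the point-biserial correlation r between the
#' (alpha power) values and the binary class indicator, and returns
#' sign(r) * r^2. Right-directed shifts are coded as the positive class, so
#' positive values mean higher power for shifts to the right.
#'
#' @param X trials x electrodes matrix of power values (or a
#'   \linkS4class{FeatureMatrix}).
#' @param right logical vector: TRUE for trials with right-directed shifts.
#' @return data.frame with columns \code{electrode}, \code{sgn_r2},
#'   \code{degenerate} (TRUE where the electrode had zero variance and the
#'   value was set to 0).
#' @export
signedR2Map <- function(X, right) {
  if (methods::is(X, "FeatureMatrix")) {
    electrodes <- X@electrodes
    X <- X@X
  } else {
    X <- as.matrix(X)
    electrodes <- colnames(X)
    if (is.null(electrodes)) electrodes <- paste0("e", seq_len(ncol(X)))
  }
  right <- as.logical(right)
  if (length(right) != nrow(X))
    stop("one class indicator per trial required")
  if (!any(right) || all(right))
    stop("both pooled classes must be non-empty")
  g <- as.numeric(right)
  out <- data.frame(electrode = electrodes, sgn_r2 = 0, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    if (stats::sd(X[, j]) == 0) {
      out$degenerate[j] <- TRUE
    } else {
      r <- stats::cor(X[, j], g)
      out$sgn_r2[j] <- sign(r) * r^2
    }
  }
  out
}

#' Pool trials into left- vs right-directed shifts
#'
#' Restricts a feature matrix to the two left and two right target discs and
#' returns the pooled class indicator (TRUE = right).
#'
#' @param fm a \linkS4class{FeatureMatrix} with direction labels.
#' @return list with \code{X} (restricted matrix), \code{right} (logical) and
#'   \code{electrodes}.
#' @export
poolLeftRight <- function(fm) {
  pd <- pooledDirections()
  keep <- fm@direction %in% c(pd$left, pd$right)
  list(X = fm@X[keep, , drop = FALSE],
       right = fm@direction[keep] %in% pd$right,
       electrodes = fm@electrodes)
}

#' One-way ANOVA with Tukey-Kramer post-hoc tests on peak accuracies
#'
#' @param peaks data.frame with columns \code{subject}, \code{subset}
#'   (grouping factor) and \code{peak}.
#' @return list with \code{F}, \code{p}, \code{df} (numerator, denominator)
#'   and \code{tukey} (data.frame of pairwise contrasts with adjusted
#'   p-values and confidence bounds).
#' @export
peakAnova <- function(peaks) {
  peaks$subset <- factor(peaks$subset)
  fit <- stats::aov(peak ~ subset, data = peaks)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$subset
  tukey <- data.frame(contrast = rownames(tk), tk, row.names = NULL)
  names(tukey) <- c("contrast", "diff", "lwr", "upr", "p_adj")
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), tukey = tukey)
}

#' Hemisphere-subset comparison of decoding performance
#'
#' Reruns the all-pairs classification per subject using only left-hemisphere
#' posterior electrodes, only right-hemisphere ones, or all nine, and
#' compares the per-subject peak accuracies across the three electrode
#' subsets with a one-way ANOVA and Tukey-Kramer post-hoc contrasts.
#'
#' @param epochsList list of CSD-filtered \linkS4class{EpochSet}s, one per
#'   subject.
#' @param subsets named list of electrode subsets (default
#'   [hemisphereSubsets()]).
#' @param seed integer seed for the CV fold assignments.
#' @param ... further arguments passed to [allPairsAnalysis()].
#' @return list with \code{peaks} (data.frame subject x subset) and the
#'   [peakAnova()] results.
#' @export
hemisphereComparison <- function(epochsList, subsets = hemisphereSubsets(),
                                 seed = 1L, ...) {
  rows <- list()
  for (i in seq_along(epochsList)) {
    for (nm in names(subsets)) {
      res <- allPairsAnalysis(epochsList[[i]], electrodes = subsets[[nm]],
                              seed = seed + 97 * i, ...)
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, subset = nm, peak = res$peakAccuracy,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  c(list(peaks = peaks), peakAnova(peaks))
}

#' EOG confound classification
#'
#' Applies the identical nested-CV logistic regression machinery to features
#' derived from the two bipolar EOG channels (vertical Fp2-EOGvu, horizontal
#' F10-F9): the 0-2000 ms post-cue time series, low-pass filtered and
#' decimated to a fixed number of samples per channel. High EOG accuracy with
#' chance EEG accuracy (or vice versa) indicates a dissociation between
#' ocular activity and posterior alpha modulation.
#'
#' @param recording task \linkS4class{Recording} containing Fp2, EOGvu, F9,
#'   F10.
#' @param trials the session's trial table.
#' @param windowMs post-cue feature window (default \code{c(0, 2000)}).
#' @param lowpassHz low-pass cutoff for the ocular deflections (default 20).
#' @param nSamplesPerChannel decimated samples per EOG channel (default 40,
#'   so 80 features).
#' @param latencyFilter trials to keep (default 2000 ms latency).
#' @param lambdaGrid,outerFolds,innerFolds,minTrials,seed see [nestedCV()].
#' @return list like [allPairsAnalysis()]: \code{results}, \code{summary},
#'   \code{peakAccuracy}, \code{bestPair}.
#' @export
eogConfound <- function(recording, trials, windowMs = c(0, 2000),
                        lowpassHz = 20, nSamplesPerChannel = 40,
                        latencyFilter = 2000,
                        lambdaGrid = defaultLambdaGrid(), outerFolds = 10,
                        innerFolds = 5, minTrials = 10, seed = 1L) {
  ## subset to the four EOG-relevant channels before deriving bipolars so
  ## the full recording is never copied
  rec <- selectChannels(recording, c("Fp2", "EOGvu", "F10", "F9"))
  rec <- selectChannels(addBipolarEOG(rec), c("EOGv", "EOGh"))
  epochs <- epochRecording(rec, trials, windowMs = windowMs,
                           latencyFilter = latencyFilter)
  sfreq <- epochs@sfreq
  bf <- signal::butter(4, lowpassHz / (sfreq / 2), type = "low")
  d <- dim(epochs@data)
  idx <- unique(round(seq(1, d[3], length.out = nSamplesPerChannel)))
  X <- matrix(0, d[1], 2 * length(idx))
  for (ci in 1:2) {
    for (tr in seq_len(d[1])) {
      filt <- signal::filtfilt(bf, epochs@data[tr, ci, ])
      X[tr, (ci - 1) * length(idx) + seq_along(idx)] <- filt[idx]
    }
  }
  y <- epochs@trials$direction
  pairs <- utils::combn(1:6, 2)
  results <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    keep <- y %in% pairs[, k]
    cnt <- table(factor(y[keep], levels = pairs[, k]))
    if (any(cnt < minTrials))
      stop("insufficient trials for pair (", pairs[1, k], ", ", pairs[2, k],
           ")")
    results[[k]] <- nestedCV(X[keep, , drop = FALSE], y[keep],
                             lambdaGrid = lambdaGrid,
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

#' Correlation between EEG- and EOG-based accuracies
#'
#' Pools direction pairs (across subjects) that reached significance in
#' either modality and computes the Pearson correlation between the EEG and
#' EOG accuracies of those pairs.
#'
#' @param eegSummaries,eogSummaries lists (one element per subject) of the
#'   15-row summary data.frames from [allPairsAnalysis()] and
#'   [eogConfound()].
#' @param alpha significance threshold for pair selection (default 0.05).
#' @return list with \code{r}, \code{p}, \code{n} (pairs entering) and the
#'   pooled data.frame.
#' @export
eegEogAccuracyCorrelation <- function(eegSummaries, eogSummaries,
                                      alpha = 0.05) {
  stopifnot(length(eegSummaries) == length(eogSummaries))
  rows <- list()
  for (i in seq_along(eegSummaries)) {
    a <- eegSummaries[[i]]
    b <- eogSummaries[[i]]
    sel <- a$p < alpha | b$p < alpha
    if (any(sel))
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, eeg = a$accuracy[sel], eog = b$accuracy[sel])
  }
  pooled <- if (length(rows)) do.call(rbind, rows)
            else data.frame(subject = integer(), eeg = numeric(),
                            eog = numeric())
  if (nrow(pooled) < 3 || stats::sd(pooled$eeg) == 0 ||
      stats::sd(pooled$eog) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(pooled),
                pooled = pooled))
  ct <- stats::cor.test(pooled$eeg, pooled$eog)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pooled),
       pooled = pooled)
}
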