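#' @import methods
NULL

#' Continuous multi-channel recording
#'
#' Holds a continuous multi-channel EEG/EOG signal in microvolts together with
#' its sampling rate, channel labels and an event table. Events use 0-based
#' sample indexing: an event with \code{onset_sample = 0} starts at the first
#' sample of the recording.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot sfreq sampling rate in Hz.
#' @slot labels character vector of unique channel labels, one per row of
#'   \code{data}.
#' @slot events data.frame with columns \code{onset_sample} (0-based),
#'   \code{duration} (samples) and \code{label}, sorted by onset.
#'
#' @exportClass Recording
setClass("Recording",
  slots = c(data = "matrix", sfreq = "numeric", labels = "character",
            events = "data.frame"))

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "number of data rows must equal number of labels")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  ev <- object@events
  need <- c("onset_sample", "duration", "label")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have columns onset_sample, duration, label")
  } else if (nrow(ev) > 0) {
    if (is.unsorted(ev$onset_sample))
      msg <- c(msg, "events must be sorted by onset_sample")
    if (any(ev$onset_sample < 0) || any(ev$onset_sample >= ncol(object@data)))
      msg <- c(msg, "event onsets must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Set of epochs cut around cue onset
#'
#' Trials x channels x time array of signal segments cut relative to an event
#' (by convention, cue onset at t = 0), with the time axis in milliseconds and
#' a linked trial table.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot times numeric vector of epoch times in ms relative to the alignment
#'   event; strictly increasing with uniform step \code{1000/sfreq}.
#' @slot sfreq sampling rate in Hz.
#' @slot labels channel labels.
#' @slot trials data.frame of per-trial metadata, one row per epoch.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  slots = c(data = "array", times = "numeric", sfreq = "numeric",
            labels = "character", trials = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x time)")
  else {
    if (d[2] != length(object@labels))
      msg <- c(msg, "second dimension must match number of labels")
    if (d[3] != length(object@times))
      msg <- c(msg, "third dimension must match length of times")
    if (nrow(object@trials) != d[1])
      msg <- c(msg, "trial table must have one row per epoch")
  }
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    step <- 1000 / object@sfreq
    if (max(abs(dt - step)) > 1e-6 * step)
      msg <- c(msg, "times must have uniform step 1000/sfreq")
  }
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Morlet wavelet time-frequency decomposition
#'
#' Complex wavelet coefficients, their amplitude, or the across-trial
#' phase-locking factor (PLF). In \code{"complex"} and \code{"amplitude"} mode
#' the array is trials x channels x freqs x times; in \code{"plf"} mode it is
#' channels x freqs x times. The \code{valid} matrix (freqs x times) marks
#' coefficients whose wavelet support lies fully inside the epoch; entries
#' outside it are edge-contaminated and are reported rather than silently
#' zero-padded.
#'
#' @slot coeffs complex or numeric array (see above).
#' @slot freqs wavelet center frequencies in Hz, strictly increasing.
#' @slot times coefficient times in ms.
#' @slot labels channel labels.
#' @slot mode one of \code{"complex"}, \code{"amplitude"}, \code{"plf"}.
#' @slot valid logical matrix freqs x times; TRUE where the wavelet support is
#'   fully inside the epoch.
#' @slot halfWidthMs per-frequency wavelet half-support in ms.
#' @slot nExcluded number of zero-magnitude coefficients excluded from a PLF.
#'
#' @exportClass TFRResult
setClass("TFRResult",
  slots = c(coeffs = "array", freqs = "numeric", times = "numeric",
            labels = "character", mode = "character", valid = "matrix",
            halfWidthMs = "numeric", nExcluded = "numeric"))

setValidity("TFRResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("complex", "amplitude", "plf"))
    msg <- c(msg, "mode must be complex, amplitude or plf")
  nd <- length(dim(object@coeffs))
  expnd <- if (object@mode == "plf") 3L else 4L
  if (nd != expnd)
    msg <- c(msg, sprintf("coeffs must have %d dimensions in %s mode",
                          expnd, object@mode))
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (!all(dim(object@valid) == c(length(object@freqs),
                                  length(object@times))))
    msg <- c(msg, "valid mask must be freqs x times")
  if (object@mode == "plf") {
    v <- object@coeffs[is.finite(object@coeffs)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "PLF values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Spherical-spline basis for current source density estimation
#'
#' Precomputed matrices for the spherical-spline surface Laplacian. \code{G}
#' holds the spline kernel g(cos theta_ij), \code{H} its Laplacian counterpart
#' h(cos theta_ij), and \code{transform} the ready-to-apply linear map such
#' that \code{CSD = transform \%*\% V} for a channels x samples potential
#' matrix \code{V}.
#'
#' @slot G symmetric spline matrix (channels x channels).
#' @slot H Laplacian spline matrix.
#' @slot m integer spline stiffness order (>= 2).
#' @slot lambda ridge regularizer added to G before solving.
#' @slot nTerms number of Legendre series terms (>= 20).
#' @slot labels channel labels the basis was built for (order matters).
#' @slot transform precomputed CSD transform matrix.
#'
#' @exportClass SplineBasis
setClass("SplineBasis",
  slots = c(G = "matrix", H = "matrix", m = "numeric", lambda = "numeric",
            nTerms = "numeric", labels = "character", transform = "matrix"))

setValidity("SplineBasis", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@G, t(object@G), tolerance = 1e-8)))
    msg <- c(msg, "G must be symmetric")
  dg <- diag(object@G)
  if (max(abs(dg - dg[1])) > 1e-8 * max(abs(dg)))
    msg <- c(msg, "diagonal of G must be constant")
  if (object@nTerms < 20)
    msg <- c(msg, "nTerms must be >= 20")
  if (!all(is.finite(object@G)) || !all(is.finite(object@H)))
    msg <- c(msg, "spline matrices must be finite")
  if (length(msg)) msg else TRUE
})

#' Trials x electrodes bandpower feature matrix
#'
#' @slot X numeric matrix, trials x electrodes, of alpha bandpower features
#'   (non-negative, finite).
#' @slot direction integer cued direction (1-6) per trial (row).
#' @slot electrodes ordered electrode labels, one per column.
#' @slot trialId integer trial identifiers.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(X = "matrix", direction = "integer", electrodes = "character",
            trialId = "integer"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@X)))
    msg <- c(msg, "features must be finite")
  if (min(object@X) < 0)
    msg <- c(msg, "bandpower features must be non-negative")
  if (nrow(object@X) != length(object@direction))
    msg <- c(msg, "one direction label per row required")
  if (ncol(object@X) != length(object@electrodes))
    msg <- c(msg, "one electrode label per column required")
  if (length(msg)) msg else TRUE
})

#' L2-regularized logistic regression model
#'
#' Minimizer of mean negative log-likelihood + (lambda/2) * ||w||^2, intercept
#' unpenalized.
#'
#' @slot w weight vector, one entry per feature.
#' @slot b intercept.
#' @slot lambda L2 regularization strength.
#' @slot converged whether the gradient tolerance was reached.
#' @slot gradNorm infinity norm of the objective gradient at the solution.
#' @slot iterations Newton iterations used.
#'
#' @exportClass LogRegModel
setClass("LogRegModel",
  slots = c(w = "numeric", b = "numeric", lambda = "numeric",
            converged = "logical", gradNorm = "numeric",
            iterations = "numeric"))

setValidity("LogRegModel", function(object) {
  if (!all(is.finite(object@w)) || !is.finite(object@b))
    "weights and intercept must be finite" else TRUE
})

#' Nested cross-validation result for one direction pair
#'
#' @slot pair integer vector of the two direction codes.
#' @slot predictions data.frame with one row per trial: \code{trial_id},
#'   \code{fold}, \code{actual}, \code{predicted} (direction codes).
#' @slot accuracy pooled fraction of correct outer-test predictions.
#' @slot lambdaPerFold chosen regularization strength per outer fold.
#' @slot mcnemarP two-sided McNemar p-value versus the majority-class
#'   assignment.
#' @slot nTrials number of trials entering the analysis.
#' @slot degenerate TRUE when the McNemar discordance count was zero.
#'
#' @exportClass PairCVResult
setClass("PairCVResult",
  slots = c(pair = "integer", predictions = "data.frame",
            accuracy = "numeric", lambdaPerFold = "numeric",
            mcnemarP = "numeric", nTrials = "integer",
            degenerate = "logical"))

setValidity("PairCVResult", function(object) {
  msg <- character()
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must contain exactly two direction codes")
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must lie in [0, 1]")
  if (nrow(object@predictions) != object@nTrials)
    msg <- c(msg, "exactly one prediction per trial required")
  if (object@mcnemarP < 0 || object@mcnemarP > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Generative parameters of one synthetic subject
#'
#' Encodes the subject-level quantities the simulator varies across a cohort:
#' resting posterior alpha amplitude, strength of the direction-dependent late
#' alpha synchronization, left-hemisphere asymmetry, ocular direction
#' coupling, sensor noise, and reaction-time parameters.
#'
#' @slot subjectId subject identifier.
#' @slot alphaAmp posterior resting alpha amplitude in microvolts (> 0).
#' @slot effectKappa direction-dependent late-synchronization gain (>= 0);
#'   0 means the task signal carries no information about direction.
#' @slot hemiAsym left-hemisphere asymmetry in [0, 1]; 0 = symmetric, 1 =
#'   left-hemisphere sensitivity to right-directed shifts doubled.
#' @slot eogConfound gain coupling ocular deflections to cue direction (>= 0).
#' @slot noiseSd white sensor noise standard deviation (microvolts).
#' @slot rtGeoValid,rtGeoInvalid geometric-mean reaction times (ms) for
#'   validly and invalidly cued targets.
#' @slot rtLogSd lognormal sigma of reaction times.
#' @slot pCorrect probability of a correct symbol response.
#' @slot seed integer seed for all randomness tied to this subject.
#'
#' @exportClass SubjectParams
setClass("SubjectParams",
  slots = c(subjectId = "character", alphaAmp = "numeric",
            effectKappa = "numeric", hemiAsym = "numeric",
            eogConfound = "numeric", noiseSd = "numeric",
            rtGeoValid = "numeric", rtGeoInvalid = "numeric",
            rtLogSd = "numeric", pCorrect = "numeric", seed = "numeric"))

setValidity("SubjectParams", function(object) {
  msg <- character()
  if (object@alphaAmp <= 0) msg <- c(msg, "alphaAmp must be > 0")
  if (object@effectKappa < 0) msg <- c(msg, "effectKappa must be >= 0")
  if (object@hemiAsym < 0 || object@hemiAsym > 1)
    msg <- c(msg, "hemiAsym must lie in [0, 1]")
  if (object@eogConfound < 0) msg <- c(msg, "eogConfound must be >= 0")
  if (object@rtGeoInvalid < object@rtGeoValid)
    msg <- c(msg, "rtGeoInvalid must be >= rtGeoValid")
  if (object@pCorrect < 0 || object@pCorrect > 1)
    msg <- c(msg, "pCorrect must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
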