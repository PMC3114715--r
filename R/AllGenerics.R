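#' Channel labels of an object
#'
#' @param x a \linkS4class{Recording}, \linkS4class{EpochSet},
#'   \linkS4class{TFRResult} or \linkS4class{SplineBasis}.
#' @return character vector of channel labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Sampling rate in Hz
#'
#' @param x a \linkS4class{Recording} or \linkS4class{EpochSet}.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Event table of a recording
#'
#' @param x a \linkS4class{Recording}.
#' @return data.frame with columns \code{onset_sample} (0-based),
#'   \code{duration}, \code{label}.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' Per-trial metadata linked to an object
#'
#' @param x an \linkS4class{EpochSet} or \linkS4class{FeatureMatrix}.
#' @return data.frame (for \code{EpochSet}) or integer direction codes (for
#'   \code{FeatureMatrix}).
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' Numeric payload of a container
#'
#' Returns the raw numeric content: channels x samples for a
#' \linkS4class{Recording}, trials x channels x time for an
#' \linkS4class{EpochSet}, the coefficient array for a
#' \linkS4class{TFRResult}, the trials x electrodes matrix for a
#' \linkS4class{FeatureMatrix}.
#'
#' @param x the container.
#' @return matrix or array.
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' Pooled cross-validated accuracy
#'
#' @param x a \linkS4class{PairCVResult}.
#' @return fraction of correct outer-test predictions.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

setMethod("channelLabels", "Recording", function(x) x@labels)
setMethod("channelLabels", "EpochSet", function(x) x@labels)
setMethod("channelLabels", "TFRResult", function(x) x@labels)
setMethod("channelLabels", "SplineBasis", function(x) x@labels)

setMethod("samplingRate", "Recording", function(x) x@sfreq)
setMethod("samplingRate", "EpochSet", function(x) x@sfreq)

setMethod("eventTable", "Recording", function(x) x@events)
setMethod("trialInfo", "EpochSet", function(x) x@trials)
setMethod("trialInfo", "FeatureMatrix", function(x) x@direction)

setMethod("signalData", "Recording", function(x) x@data)
setMethod("signalData", "EpochSet", function(x) x@data)
setMethod("signalData", "TFRResult", function(x) x@coeffs)
setMethod("signalData", "FeatureMatrix", function(x) x@X)

setMethod("accuracy", "PairCVResult", function(x) x@accuracy)

#' @rdname epochTimes
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Time axis in milliseconds
#'
#' @param x an \linkS4class{EpochSet} or \linkS4class{TFRResult}.
#' @return numeric vector of times in ms relative to cue onset.
#' @name epochTimes
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)
setMethod("epochTimes", "TFRResult", function(x) x@times)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@sfreq,
              ncol(object@data) / object@sfreq, nrow(object@events)))
  cat("  channels:", paste(utils::head(object@labels, 8), collapse = ", "),
      if (length(object@labels) > 8) "..." else "", "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  time: %g to %g ms relative to cue onset\n",
              min(object@times), max(object@times)))
})

setMethod("show", "TFRResult", function(object) {
  cat(sprintf("TFRResult [%s]: %s; %d freqs (%g-%g Hz), %d times\n",
              object@mode,
              paste(dim(object@coeffs), collapse = " x "),
              length(object@freqs), min(object@freqs), max(object@freqs),
              length(object@times)))
})

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf(
    "SplineBasis: %d channels, m = %d, lambda = %g, %d Legendre terms\n",
    nrow(object@G), object@m, object@lambda, object@nTerms))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d electrodes (%s)\n",
              nrow(object@X), ncol(object@X),
              paste(utils::head(object@electrodes, 4), collapse = ", ")))
  cat("  directions:", paste(names(table(object@direction)),
                             as.integer(table(object@direction)),
                             sep = ":", collapse = "  "), "\n")
})

setMethod("show", "LogRegModel", function(object) {
  cat(sprintf(
    "LogRegModel: %d features, lambda = %g, |grad| = %.2g (%s in %d iter)\n",
    length(object@w), object@lambda, object@gradNorm,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
})

setMethod("show", "PairCVResult", function(object) {
  cat(sprintf(
    "PairCVResult: directions %d vs %d, accuracy %.1f%% (n = %d), McNemar p = %.3g\n",
    object@pair[1], object@pair[2], 100 * object@accuracy, object@nTrials,
    object@mcnemarP))
})

setMethod("show", "SubjectParams", function(object) {
  cat(sprintf(
    "SubjectParams '%s': alphaAmp %.2f uV, kappa %.2f, hemiAsym %.2f, eog %.2f, seed %d\n",
    object@subjectId, object@alphaAmp, object@effectKappa, object@hemiAsym,
    object@eogConfound, object@seed))
})
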