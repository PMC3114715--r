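## Welch-method alpha bandpower features. The 500-2000 ms post-cue window is
## split into 8 segments with 50% overlap (segment length
## L = floor(2 N / (nSegments + 1)) samples, guaranteeing exactly nSegments
## segments), each segment is Hamming-tapered, the one-sided periodogram is
## taper-power normalized, PSDs are averaged across segments, and the feature
## is the mean PSD over bins whose center frequency lies in [8, 12] Hz
## inclusive.

.hamming <- function(L) 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))

## Welch PSD of a time x series matrix; returns list(freq, psd) with psd
## bins x series (one-sided density)
.welchPsdMat <- function(x, sfreq, nSegments = 8, overlap = 0.5) {
  N <- nrow(x)
  L <- floor(2 * N / (nSegments + 1))
  if (L < 2)
    stop("window too short to split into ", nSegments, " segments")
  step <- floor(L * (1 - overlap))
  if (step < 1) stop("overlap too large for segment length ", L)
  starts <- (seq_len(nSegments) - 1L) * step
  if (starts[nSegments] + L > N)
    stop("window too short to split into ", nSegments,
         " segments of ", L, " samples")
  w <- .hamming(L)
  norm <- sfreq * sum(w^2)
  nb <- floor(L / 2) + 1
  acc <- matrix(0, nb, ncol(x))
  for (s in starts) {
    seg <- x[s + seq_len(L), , drop = FALSE] * w
    P <- Mod(stats::mvfft(seg))^2 / norm
    P <- P[seq_len(nb), , drop = FALSE]
    ## one-sided density: double the interior bins
    dbl <- 2:(nb - if (L %% 2 == 0) 1 else 0)
    P[dbl, ] <- 2 * P[dbl, ]
    acc <- acc + P
  }
  list(freq = (seq_len(nb) - 1) * sfreq / L, psd = acc / nSegments)
}

#' Welch alpha bandpower features for every channel
#'
#' Estimates per-trial, per-channel bandpower in the analysis window using
#' the Welch method and returns the trials x channels feature matrix.
#'
#' @param epochs an \linkS4class{EpochSet} (typically after CSD).
#' @param windowMs analysis window in ms, half-open, default
#'   \code{c(500, 2000)} (the late alpha synchronization).
#' @param bandHz frequency band, default \code{c(8, 12)}; bins with center
#'   frequency in the closed band are averaged.
#' @param nSegments number of Welch segments (default 8).
#' @param overlap segment overlap fraction (default 0.5).
#' @return a \linkS4class{FeatureMatrix} over all channels of \code{epochs}.
#' @export
welchBandpower <- function(epochs, windowMs = c(500, 2000),
                           bandHz = c(8, 12), nSegments = 8, overlap = 0.5) {
  sfreq <- epochs@sfreq
  if (bandHz[2] > sfreq / 2)
    stop("band [", bandHz[1], ", ", bandHz[2],
         "] Hz exceeds the Nyquist frequency ", sfreq / 2, " Hz")
  sel <- epochs@times >= windowMs[1] & epochs@times < windowMs[2]
  if (sum(sel) < nSegments)
    stop("analysis window (", sum(sel), " samples) shorter than the number ",
         "of segments (", nSegments, ")")
  d <- dim(epochs@data)
  ## time x (trials * channels)
  m <- aperm(epochs@data[, , sel, drop = FALSE], c(3, 1, 2))
  dim(m) <- c(sum(sel), d[1] * d[2])
  ps <- .welchPsdMat(m, sfreq, nSegments, overlap)
  band <- ps$freq >= bandHz[1] & ps$freq <= bandHz[2]
  if (!any(band))
    stop("no PSD bins fall inside [", bandHz[1], ", ", bandHz[2], "] Hz; ",
         "increase the window length or sampling rate")
  feat <- colMeans(ps$psd[band, , drop = FALSE])
  X <- matrix(feat, d[1], d[2])
  dirs <- if ("direction" %in% names(epochs@trials))
    as.integer(epochs@trials$direction) else rep(NA_integer_, d[1])
  ids <- if ("trial_id" %in% names(epochs@trials))
    as.integer(epochs@trials$trial_id) else seq_len(d[1])
  new("FeatureMatrix", X = X, direction = dirs, electrodes = epochs@labels,
      trialId = ids)
}

#' Restrict a feature matrix to one direction pair
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param pair integer vector of two distinct direction codes.
#' @param minTrials minimum trials required per direction (default 10).
#' @return the feature matrix restricted to trials of the two directions.
#' @export
featurePair <- function(fm, pair, minTrials = 10) {
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must contain two distinct direction codes")
  keep <- fm@direction %in% pair
  cnt <- table(factor(fm@direction[keep], levels = pair))
  if (any(cnt < minTrials))
    stop("insufficient trials for pair (", pair[1], ", ", pair[2], "): ",
         paste(sprintf("direction %d has %d", pair, as.integer(cnt)),
               collapse = ", "))
  new("FeatureMatrix", X = fm@X[keep, , drop = FALSE],
      direction = fm@direction[keep], electrodes = fm@electrodes,
      trialId = fm@trialId[keep])
}

#' Build the classifier input for one direction pair
#'
#' Convenience wrapper: selects the posterior electrode subset, computes
#' Welch alpha bandpower, and restricts trials to the two directions.
#'
#' @param epochs an \linkS4class{EpochSet} after CSD filtering.
#' @param electrodes electrode subset (default the nine
#'   parieto-occipital/occipital channels).
#' @param pair two distinct direction codes.
#' @param windowMs,bandHz,nSegments,overlap passed to [welchBandpower()].
#' @param minTrials minimum trials per direction (default 10).
#' @return a \linkS4class{FeatureMatrix} with binary direction labels.
#' @export
buildFeatures <- function(epochs, electrodes = posteriorElectrodes(), pair,
                          windowMs = c(500, 2000), bandHz = c(8, 12),
                          nSegments = 8, overlap = 0.5, minTrials = 10) {
  fm <- welchBandpower(selectChannels(epochs, electrodes), windowMs, bandHz,
                       nSegments, overlap)
  featurePair(fm, pair, minTrials)
}
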