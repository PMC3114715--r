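## Morlet wavelet time-frequency decomposition. Wavelets are
## Gaussian-windowed complex exponentials with a constant cycle count q,
## sigma_t = q / (2 pi f), truncated at +/- k sigma_t and normalized to unit
## energy. With the defaults (q = 3.5, k = 3) the widest wavelet (4 Hz) has a
## half-support of k q / (2 pi * 4) = 417.8 ms, so a baseline ending at
## -419 ms cannot contain post-cue activity. Coefficients whose wavelet
## support sticks out of the epoch are edge-contaminated; they are kept but
## flagged in the validity mask rather than silently zero-padded.

.morletWavelet <- function(freq, sfreq, cycles, truncK) {
  sigma <- cycles / (2 * pi * freq)
  hw <- floor(truncK * sigma * sfreq)
  tw <- (-hw:hw) / sfreq
  w <- exp(2i * pi * freq * tw) * exp(-tw^2 / (2 * sigma^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet transform of an epoch set
#'
#' Convolves every trial and channel with complex Morlet wavelets at the
#' requested center frequencies. Returns complex coefficients; use
#' [tfrAmplitude()], [baselineCorrect()] and [plf()] downstream.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param freqs center frequencies in Hz (default 4-30 Hz in 1 Hz steps).
#' @param cycles constant cycle count q of the wavelet family (default 3.5).
#' @param truncK Gaussian truncation at +/- k sigma_t (default 3).
#' @param channels optional channel subset to transform.
#' @param decim keep every \code{decim}-th time sample of the output
#'   (default 1 = all).
#' @return a \linkS4class{TFRResult} in \code{"complex"} mode
#'   (trials x channels x freqs x times).
#' @export
morletTransform <- function(epochs, freqs = 4:30, cycles = 3.5, truncK = 3,
                            channels = NULL, decim = 1L) {
  if (any(freqs <= 0)) stop("wavelet center frequencies must be > 0")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly increasing")
  if (!is.null(channels)) epochs <- selectChannels(epochs, channels)
  d <- dim(epochs@data)
  nT <- d[1]; nC <- d[2]; n <- d[3]
  sfreq <- epochs@sfreq
  wavelets <- lapply(freqs, .morletWavelet, sfreq = sfreq, cycles = cycles,
                     truncK = truncK)
  hws <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, 0L)
  if (2 * max(hws) + 1 > n)
    stop("epoch (", n, " samples) is shorter than the widest wavelet (",
         2 * max(hws) + 1, " samples); extend the epoch or reduce cycles")
  keep <- seq(1L, n, by = as.integer(decim))
  L <- stats::nextn(n + 2L * max(hws), c(2, 3, 5))
  ## FFT of zero-padded signals, one L x trials matrix per channel
  out <- array(complex(1), c(nT, nC, length(freqs), length(keep)))
  valid <- matrix(FALSE, length(freqs), length(keep))
  for (fi in seq_along(freqs)) {
    hw <- hws[fi]
    wpad <- complex(L)
    wpad[seq_len(2L * hw + 1L)] <- wavelets[[fi]]
    wf <- stats::fft(wpad)
    valid[fi, ] <- keep - hw >= 1L & keep + hw <= n
    for (ci in seq_len(nC)) {
      sig <- matrix(0, L, nT)
      sig[seq_len(n), ] <- t(epochs@data[, ci, ])
      co <- stats::mvfft(stats::mvfft(sig) * wf, inverse = TRUE) / L
      out[, ci, fi, ] <- t(co[hw + keep, , drop = FALSE])
    }
  }
  hwMs <- hws / sfreq * 1000
  new("TFRResult", coeffs = out, freqs = as.numeric(freqs),
      times = epochs@times[keep], labels = epochs@labels, mode = "complex",
      valid = valid, halfWidthMs = hwMs, nExcluded = 0)
}

#' Amplitude of a complex TFR
#'
#' @param tfr a \linkS4class{TFRResult} in complex mode.
#' @return the TFR with \code{coeffs = Mod(coeffs)} and mode
#'   \code{"amplitude"}.
#' @export
tfrAmplitude <- function(tfr) {
  if (tfr@mode != "complex") stop("tfrAmplitude() requires complex mode")
  methods::initialize(tfr, coeffs = Mod(tfr@coeffs), mode = "amplitude")
}

#' Baseline-correct a TFR amplitude map
#'
#' Subtracts (or divides by) the mean amplitude in a pre-cue baseline window,
#' per trial, channel and frequency. The baseline window must end at or
#' before minus the half-support of the widest wavelet, otherwise post-cue
#' activity would leak into the baseline and the call fails hard.
#'
#' @param tfr a \linkS4class{TFRResult} in amplitude mode.
#' @param windowMs baseline window, default \code{c(-800, -419)}.
#' @param mode \code{"subtract"} (default) or \code{"relative"} (divide).
#' @return baseline-corrected \linkS4class{TFRResult}.
#' @export
baselineCorrect <- function(tfr, windowMs = c(-800, -419),
                            mode = c("subtract", "relative")) {
  mode <- match.arg(mode)
  if (tfr@mode != "amplitude")
    stop("baselineCorrect() requires an amplitude-mode TFR")
  maxHw <- max(tfr@halfWidthMs)
  if (windowMs[2] > -maxHw + 1e-9)
    stop(sprintf(paste0("baseline window end (%g ms) would leak post-cue ",
                        "activity: it must be <= -%.1f ms, half the width ",
                        "of the widest wavelet"), windowMs[2], maxHw))
  sel <- tfr@times >= windowMs[1] & tfr@times <= windowMs[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(tfr@coeffs[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  corr <- if (mode == "subtract") sweep(tfr@coeffs, c(1, 2, 3), base, "-")
          else sweep(tfr@coeffs, c(1, 2, 3), base, "/")
  methods::initialize(tfr, coeffs = corr)
}

#' Phase-locking factor across trials
#'
#' Normalizes complex wavelet coefficients to unit magnitude, averages over
#' trials, and takes the magnitude of the result: 1 = perfect phase locking
#' to cue onset, approaching 0 for random phases (for n independent uniform
#' phases the expected value is about 0.886/sqrt(n)). Zero-magnitude
#' coefficients are excluded from the average; their count is reported in the
#' \code{nExcluded} slot. Bins where all coefficients are zero get NA.
#'
#' @param tfr a \linkS4class{TFRResult} in complex mode with >= 2 trials.
#' @return a \linkS4class{TFRResult} in \code{"plf"} mode
#'   (channels x freqs x times), values in [0, 1].
#' @export
plf <- function(tfr) {
  if (tfr@mode != "complex") stop("plf() requires a complex-mode TFR")
  d <- dim(tfr@coeffs)
  if (d[1] < 2) stop("PLF requires at least 2 trials")
  mag <- Mod(tfr@coeffs)
  zero <- mag == 0
  u <- tfr@coeffs / ifelse(zero, 1, mag)
  u[zero] <- 0
  num <- apply(u, c(2, 3, 4), sum)
  cnt <- d[1] - apply(zero, c(2, 3, 4), sum)
  val <- Mod(num) / ifelse(cnt == 0, NA_real_, cnt)
  methods::initialize(tfr, coeffs = val, mode = "plf",
                      nExcluded = sum(zero))
}
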