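## Resting-state alpha index: after CSD filtering, the spectral peak in the
## 8-12 Hz band of the eyes-closed phases is extracted per electrode; the
## index pools (averages) the peak powers of a symmetric parieto-occipital
## electrode pair and is correlated with peak decoding accuracy across
## subjects.

## Welch PSD with fixed segment length over a time x series matrix
.welchPsdFixedLen <- function(x, sfreq, segLen, overlap = 0.5) {
  N <- nrow(x)
  L <- as.integer(segLen)
  if (N < L) stop("phase shorter than one Welch segment")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(0L, N - L, by = step)
  w <- .hamming(L)
  norm <- sfreq * sum(w^2)
  nb <- floor(L / 2) + 1
  acc <- matrix(0, nb, ncol(x))
  for (s in starts) {
    seg <- x[s + seq_len(L), , drop = FALSE] * w
    P <- Mod(stats::mvfft(seg))^2 / norm
    P <- P[seq_len(nb), , drop = FALSE]
    dbl <- 2:(nb - if (L %% 2 == 0) 1 else 0)
    P[dbl, ] <- 2 * P[dbl, ]
    acc <- acc + P
  }
  list(freq = (seq_len(nb) - 1) * sfreq / L, psd = acc / length(starts),
       nSegments = length(starts))
}

## Welch PSD of the eyes-closed phases of a (CSD-filtered) resting recording,
## averaged over segments of all phases; returns freq x channels
.restingPsd <- function(resting, phaseLabel = "eyes_closed", segSec = 2,
                        overlap = 0.5) {
  ev <- resting@events
  ph <- ev[ev$label == phaseLabel, , drop = FALSE]
  if (nrow(ph) < 2)
    stop("at least 2 '", phaseLabel, "' phases are required; found ",
         nrow(ph))
  L <- round(segSec * resting@sfreq)
  tot <- NULL
  nTot <- 0
  for (k in seq_len(nrow(ph))) {
    idx <- ph$onset_sample[k] + seq_len(ph$duration[k])
    seg <- t(resting@data[, idx, drop = FALSE])
    ps <- .welchPsdFixedLen(seg, resting@sfreq, L, overlap)
    tot <- if (is.null(tot)) ps$psd * ps$nSegments
           else tot + ps$psd * ps$nSegments
    nTot <- nTot + ps$nSegments
    freq <- ps$freq
  }
  list(freq = freq, psd = tot / nTot)
}

#' Alpha spectral peak of an eyes-closed resting recording
#'
#' Concatenates the eyes-closed phases, applies the CSD transform (unless
#' \code{basis = NULL} is explicitly passed with \code{csd = FALSE}),
#' estimates the Welch PSD (2 s Hamming segments, 50\% overlap by default),
#' and returns the maximum PSD value in the 8-12 Hz band and its frequency.
#'
#' @param resting resting-state \linkS4class{Recording} with
#'   \code{eyes_closed}/\code{eyes_open} phase markers.
#' @param electrode channel label to extract the peak from.
#' @param basis optional precomputed \linkS4class{SplineBasis} over the scalp
#'   channels; built from \code{montage} when NULL and \code{csd = TRUE}.
#' @param montage montage used to build the basis (default
#'   [defaultMontage()]).
#' @param csd apply CSD filtering first (default TRUE).
#' @param band alpha search band in Hz, inclusive (default \code{c(8, 12)}).
#' @param segSec Welch segment length in seconds (default 2).
#' @param overlap segment overlap (default 0.5).
#' @return list with \code{peakFreq}, \code{peakPower}, \code{degenerate}
#'   (TRUE for an all-zero spectrum, where peakPower = 0).
#' @export
alphaPeak <- function(resting, electrode, basis = NULL,
                      montage = defaultMontage(), csd = TRUE,
                      band = c(8, 12), segSec = 2, overlap = 0.5) {
  if (!electrode %in% resting@labels)
    stop("electrode ", electrode, " not present in the recording")
  if (csd) {
    scalp <- selectChannels(resting, scalpLabels())
    if (is.null(basis))
      basis <- buildSplineBasis(montage[match(scalpLabels(), montage$label), ])
    resting <- csdTransform(scalp, basis)
  }
  ps <- .restingPsd(resting, "eyes_closed", segSec, overlap)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) stop("no PSD bins inside the alpha band")
  col <- match(electrode, resting@labels)
  p <- ps$psd[sel, col]
  if (all(p == 0))
    return(list(peakFreq = NA_real_, peakPower = 0, degenerate = TRUE))
  i <- which.max(p)
  list(peakFreq = ps$freq[sel][i], peakPower = p[i], degenerate = FALSE)
}

#' Resting alpha index of a symmetric electrode pair
#'
#' Pools (averages) the eyes-closed alpha peak powers of a symmetric
#' parieto-occipital electrode pair after CSD filtering. PO3-PO4 is the
#' default; PO7-PO8 is the common alternative.
#'
#' @param resting resting-state \linkS4class{Recording}.
#' @param pair character vector of two electrode labels
#'   (default \code{c("PO3", "PO4")}).
#' @param ... passed to [alphaPeak()] (e.g. a precomputed \code{basis}).
#' @return list with \code{pair}, per-electrode \code{peakFreq} and
#'   \code{peakPower}, and \code{pooledPower} (mean of the two peak powers).
#' @export
alphaIndex <- function(resting, pair = c("PO3", "PO4"), ...) {
  miss <- setdiff(pair, resting@labels)
  if (length(miss))
    stop("electrode(s) not present: ", paste(miss, collapse = ", "))
  pk <- lapply(pair, function(e) alphaPeak(resting, e, ...))
  list(pair = pair,
       peakFreq = stats::setNames(vapply(pk, `[[`, 0, "peakFreq"), pair),
       peakPower = stats::setNames(vapply(pk, `[[`, 0, "peakPower"), pair),
       pooledPower = mean(vapply(pk, `[[`, 0, "peakPower")))
}

#' Correlate the resting alpha index with peak decoding accuracy
#'
#' Pearson correlation (two-sided) between per-subject alpha indices and peak
#' accuracies, plus the least-squares linear fit for reporting.
#'
#' @param indices numeric vector of per-subject alpha index values.
#' @param peaks numeric vector of per-subject peak accuracies.
#' @return list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n}.
#' @examples
#' correlatePredictor(c(1, 2, 3), c(2, 4, 6))  # r = 1, slope 2, intercept 0
#' @export
correlatePredictor <- function(indices, peaks) {
  if (length(indices) != length(peaks))
    stop("indices and peaks must have equal length")
  if (length(indices) < 3) stop("at least 3 subjects are required")
  if (!all(is.finite(indices)) || !all(is.finite(peaks)))
    stop("non-finite values in predictor inputs")
  if (stats::sd(indices) == 0 || stats::sd(peaks) == 0)
    stop("undefined correlation: zero variance in inputs")
  ct <- stats::cor.test(indices, peaks)
  fit <- stats::lm(peaks ~ indices)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(indices))
}
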