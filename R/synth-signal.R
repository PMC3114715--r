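## Signal-level simulator. One session is a concatenation of fixed-length
## trial slots (900 ms pre-cue, 2100 ms post-cue). Per channel the signal is
##   1/f background + white sensor noise
##   + cue-locked delta/theta transient (fixed phase across trials)
##   + narrowband (8-12 Hz) alpha process with a time-varying envelope:
##     early direction-independent dip around 500 ms, late rise from ~1600 ms
##     with multiplicative gain 1 + g0 + kappa * w(e, d).
## The topographic weight w(e, d) is a von Mises bump over the azimuth of
## posterior electrodes whose preferred direction is contralateral to the
## cued hemifield, scaled on the left hemisphere by (1 + hemiAsym) for
## right-directed shifts.

.SLOT_PRE_MS <- 900
.SLOT_POST_MS <- 2100
.BG_SD <- 6          # 1/f background amplitude, uV
.TRANS_AMP <- 10     # cue transient amplitude at the posterior peak, uV
.TRANS_FREQ <- 5     # Hz, delta/theta transient carrier
.ALPHA_DIP <- 0.6    # depth of the early desynchronization
.LATE_GAIN0 <- 0.4   # direction-independent late synchronization gain
.VM_CONC <- 2        # von Mises concentration of the direction tuning
.EOG_AMP <- 30       # ocular deflection amplitude at eogConfound = 1, uV

#' Direction geometry of the six target discs
#'
#' Discs sit at 9 degrees eccentricity at the clock positions top-right, top,
#' top-left, bottom-left, bottom and bottom-right; direction codes 1-6 step
#' anticlockwise from top-right. The returned angle is measured clockwise
#' from vertical (so positive angles are right-hemifield directions).
#'
#' @param direction integer direction code(s) in 1-6.
#' @return angle(s) in degrees clockwise from vertical.
#' @export
directionAngle <- function(direction) {
  ang <- c(60, 0, -60, -120, 180, 120)
  ang[direction]
}

#' Direction codes pooled as left- and right-hemifield shifts
#'
#' @return list with integer vectors \code{left} (the two discs with negative
#'   horizontal coordinate) and \code{right}.
#' @export
pooledDirections <- function() {
  ang <- directionAngle(1:6)
  list(left = which(ang < 0), right = which(ang > 0 & ang < 180))
}

## smooth posterior topography in [0, 1]: Gaussian in angular distance from a
## point between Oz and the inion
.posteriorWeight <- function(montage) {
  xyz <- montagePositions(montage)
  c0 <- .sph2cart(80, 180)[1, ]
  ang <- acos(pmin(1, pmax(-1, xyz %*% c0)))
  w <- exp(-(ang / 0.7)^2)
  stats::setNames(as.numeric(w), montage$label)
}

## preferred attention direction of each electrode (degrees clockwise from
## vertical): contralateral mapping of the electrode's azimuth from the
## inion, scaled so the +/-36 degree azimuth span of the parieto-occipital
## strip covers the full direction circle (every direction has a distinct
## preferred electrode; opposite directions get maximally distinct maps)
.electrodePrefAngle <- function(montage) {
  beta <- sign(montage$phi_deg) * (180 - abs(montage$phi_deg))
  stats::setNames(-5 * beta, montage$label)
}

## w(e, d) topographic direction tuning, rows = channels, cols = directions.
## Columns are normalized to equal total posterior drive so directions differ
## in topography, not overall power, then the left hemisphere is scaled by
## (1 + hemiAsym) for right-directed shifts.
.directionWeights <- function(montage, hemiAsym) {
  po <- .posteriorWeight(montage)
  psi <- .electrodePrefAngle(montage)
  delta <- directionAngle(1:6)
  w <- outer(psi, delta, function(p, d)
    exp(.VM_CONC * (cos((p - d) * pi / 180) - 1)))
  w <- w * po
  cs <- colSums(w)
  w <- w * rep(cs[1] / cs, each = nrow(w))
  w <- w / max(w[, 1])
  leftCh <- montage$phi_deg < 0
  rightDir <- delta > 0 & delta < 180
  w[leftCh, rightDir] <- w[leftCh, rightDir] * (1 + hemiAsym)
  w
}

## linear interpolation of matrix rows: row grid is uniform at rate fsc,
## target times t (seconds); returns length(t) x ncol(M)
.lerpIndex <- function(t, fsc, nr) {
  pos <- t * fsc
  i1 <- pmin(as.integer(floor(pos)) + 1L, nr - 1L)
  list(i1 = i1, w = pos - (i1 - 1L))
}

## frequency-domain shaped Gaussian noise, k channels: returns an nc x k
## matrix whose columns have amplitude spectrum `scale` (length nc). For real
## output, the real and imaginary parts of one complex column are two
## independent shaped processes, so only ceil(k/2) FFTs are needed.
.shapedNoiseMat <- function(nc, k, scale, complexOut = FALSE) {
  kz <- if (complexOut) k else as.integer(ceiling(k / 2))
  Z <- matrix(complex(real = stats::rnorm(nc * kz),
                      imaginary = stats::rnorm(nc * kz)), nc, kz) * scale
  E <- stats::mvfft(Z, inverse = TRUE) / nc
  if (complexOut) E else cbind(Re(E), Im(E))[, seq_len(k), drop = FALSE]
}

## 1/f background noise for k channels at once, unit variance per column:
## Gaussian noise shaped to a 1/f power spectrum (amplitude 1/sqrt(f),
## flattened below 0.5 Hz to avoid the DC pole). The process is generated
## band-limited to `fmax` at a coarse rate and interpolated to sfreq: above
## fmax (30 Hz, the top of the analysis band) the white sensor noise
## dominates the background anyway.
.pinkNoiseMat <- function(n, k, sfreq, fmax = 30) {
  fsc <- min(sfreq, 2.5 * fmax)
  nc <- stats::nextn(as.integer(ceiling(n * fsc / sfreq)) + 8L, c(2, 3, 5))
  idx <- c(0, seq_len(nc - 1))
  f <- pmin(idx, nc - idx) * fsc / nc
  scale <- ifelse(f == 0 | f > fmax, 0, 1 / sqrt(pmax(f, 0.5)))
  P <- .shapedNoiseMat(nc, k, scale)
  ix <- .lerpIndex((seq_len(n) - 1) / sfreq, fsc, nc)
  .lerpRowsCpp(P, ix$i1, ix$w, normalize = TRUE)
}

## narrowband alpha processes for k channels, unit variance per column:
## complex Gaussian envelopes with a Gaussian lowpass spectrum (sd = bw),
## generated at a low sample rate, interpolated to sfreq and mixed onto the
## alpha carrier -> power spectrum peaks at `center` with bandwidth ~bw
.alphaNoiseMat <- function(n, k, sfreq, center = 10, bw = 1.2) {
  fsc <- max(16, 8 * bw)
  nc <- stats::nextn(as.integer(ceiling(n * fsc / sfreq)) + 8L, c(2, 3, 5))
  kk <- c(0, seq_len(nc - 1))
  fc <- pmin(kk, nc - kk) * fsc / nc
  E <- .shapedNoiseMat(nc, k, exp(-(fc / bw)^2 / 2), complexOut = TRUE)
  t <- (seq_len(n) - 1) / sfreq
  ix <- .lerpIndex(t, fsc, nc)
  .alphaMixCpp(Re(E), Im(E), ix$i1, ix$w,
               cos(2 * pi * center * t), sin(2 * pi * center * t),
               normalize = TRUE)
}

## per-slot temporal shapes, sampled at sfreq; t in ms relative to cue onset
.slotTimes <- function(sfreq) {
  nPre <- round(.SLOT_PRE_MS * sfreq / 1000)
  nPost <- round(.SLOT_POST_MS * sfreq / 1000)
  (seq_len(nPre + nPost) - nPre - 1) * 1000 / sfreq
}

.transientShape <- function(t) {
  exp(-((t - 250) / 60)^2 / 2) *
    cos(2 * pi * .TRANS_FREQ * (t - 250) / 1000)
}

.dipShape <- function(t) exp(-((t - 500) / 180)^2 / 2) * (t > 0)
.rampShape <- function(t) stats::plogis((t - 1600) / 120) * (t > 0)
.eogShape <- function(t) stats::plogis((t - 300) / 80) * (t > 0)

#' Generate one synthetic task session
#'
#' Simulates the continuous multi-channel recording of one subject performing
#' the cued covert attention task described by the trial table. Event markers
#' (\code{"cue"} and \code{"target"}) exactly reproduce the trial table: one
#' cue and one target marker per trial, separated by the target latency.
#'
#' @param params \linkS4class{SubjectParams}.
#' @param trials trial table from [generateTrialTable()].
#' @param montage montage data.frame; must contain all 63 scalp channels and
#'   \code{EOGvu}.
#' @param sfreq sampling rate in Hz (default 1000).
#' @return a \linkS4class{Recording} with 64 channels (63 scalp + EOGvu).
#' @seealso [generateResting()], [epochRecording()]
#' @export
generateSession <- function(params, trials, montage = defaultMontage(),
                            sfreq = 1000) {
  .checkMontage(montage, c(scalpLabels(), "EOGvu"))
  labels <- c(scalpLabels(), "EOGvu")
  montage <- montage[match(labels, montage$label), ]
  nT <- nrow(trials)
  t <- .slotTimes(sfreq)
  S <- length(t)
  n <- S * nT
  nPre <- round(.SLOT_PRE_MS * sfreq / 1000)

  po <- .posteriorWeight(montage)
  ampAlpha <- params@alphaAmp * (0.15 + 0.85 * po)
  dirW <- .directionWeights(montage, params@hemiAsym)
  lateGain <- .LATE_GAIN0 * po + params@effectKappa * dirW  # ch x 6
  trans <- .transientShape(t)
  dip <- .dipShape(t)
  ramp <- .rampShape(t)
  eogU <- .eogShape(t)
  dirTrial <- trials$direction
  deltaRad <- directionAngle(dirTrial) * pi / 180
  eogH <- sin(deltaRad) * .EOG_AMP * params@eogConfound
  eogV <- cos(deltaRad) * .EOG_AMP * params@eogConfound
  eogCh <- c(F10 = 0.5, F9 = -0.5)       # horizontal dipole
  eogChV <- c(Fp2 = 0.5, EOGvu = -0.5)   # vertical dipole

  nCh <- length(labels)
  ## channels are generated in blocks to bound peak memory at long sessions
  blk <- max(1L, min(nCh, as.integer(2e7 %/% n)))
  .withSeed(params@seed, {
    data <- matrix(0, nCh, n)
    baseEnv <- 1 - .ALPHA_DIP * dip            # length S
    for (j0 in seq(1L, nCh, by = blk)) {
      jj <- j0:min(nCh, j0 + blk - 1L)
      k <- length(jj)
      W <- matrix(stats::rnorm(n * k, sd = params@noiseSd), n, k)
      P <- .pinkNoiseMat(n, k, sfreq)
      A <- .alphaNoiseMat(n, k, sfreq)
      ## fused: white + pink + envelope-modulated alpha + cue transient
      data[jj, ] <- .assembleSessionCpp(
        W, P, A, 1, .BG_SD, baseEnv, ramp, trans, .TRANS_AMP * po[jj],
        ampAlpha[jj], lateGain[jj, , drop = FALSE],
        as.integer(dirTrial))
      rm(W, P, A)
    }
    ## ocular deflections
    for (ch in names(eogCh)) {
      j <- match(ch, labels)
      data[j, ] <- data[j, ] + as.numeric(outer(eogU, eogCh[[ch]] * eogH))
    }
    for (ch in names(eogChV)) {
      j <- match(ch, labels)
      data[j, ] <- data[j, ] + as.numeric(outer(eogU, eogChV[[ch]] * eogV))
    }
    cueOnset <- (seq_len(nT) - 1L) * S + nPre        # 0-based
    targOnset <- cueOnset + round(trials$target_latency_ms * sfreq / 1000)
    events <- data.frame(
      onset_sample = as.integer(c(rbind(cueOnset, targOnset))),
      duration = 0L,
      label = rep(c("cue", "target"), nT),
      stringsAsFactors = FALSE)
    new("Recording", data = data, sfreq = sfreq, labels = labels,
        events = events)
  })
}

#' Generate a synthetic resting-state recording
#'
#' Alternating eyes-closed and eyes-open phases of exactly 15 s, separated by
#' 2 s breaks (10 cycles, about 6 minutes total). During eyes-closed phases
#' the posterior alpha process has amplitude \code{alphaAmp}; eyes-open
#' phases (and breaks) are attenuated by \code{openFactor}.
#'
#' @param params \linkS4class{SubjectParams}.
#' @param sfreq sampling rate in Hz (default 1000).
#' @param nCycles number of closed/open phase pairs (default 10).
#' @param openFactor eyes-open alpha attenuation (default 0.4).
#' @param montage montage data.frame.
#' @return a \linkS4class{Recording} with phase markers \code{"eyes_closed"}
#'   and \code{"eyes_open"} (duration = 15 s each).
#' @export
generateResting <- function(params, sfreq = 1000, nCycles = 10,
                            openFactor = 0.4, montage = defaultMontage()) {
  .checkMontage(montage, c(scalpLabels(), "EOGvu"))
  labels <- c(scalpLabels(), "EOGvu")
  montage <- montage[match(labels, montage$label), ]
  phaseN <- round(15 * sfreq)
  breakN <- round(2 * sfreq)
  nPhases <- 2L * as.integer(nCycles)
  n <- nPhases * phaseN + (nPhases - 1L) * breakN

  ## amplitude modulation: closed = 1, open/breaks = openFactor
  mod <- rep(openFactor, n)
  onset <- integer(nPhases)
  for (k in seq_len(nPhases)) {
    start <- (k - 1L) * (phaseN + breakN)     # 0-based
    onset[k] <- start
    if (k %% 2L == 1L) mod[start + seq_len(phaseN)] <- 1
  }
  po <- .posteriorWeight(montage)
  ampAlpha <- params@alphaAmp * (0.15 + 0.85 * po)

  nCh <- length(labels)
  blk <- max(1L, min(nCh, as.integer(2e7 %/% n)))
  .withSeed(params@seed + 7919, {
    data <- matrix(0, nCh, n)
    for (j0 in seq(1L, nCh, by = blk)) {
      jj <- j0:min(nCh, j0 + blk - 1L)
      k <- length(jj)
      W <- matrix(stats::rnorm(n * k, sd = params@noiseSd), n, k)
      P <- .pinkNoiseMat(n, k, sfreq)
      A <- .alphaNoiseMat(n, k, sfreq)
      data[jj, ] <- .assembleRestingCpp(W, P, A, 1, .BG_SD, mod,
                                        ampAlpha[jj])
      rm(W, P, A)
    }
    events <- data.frame(
      onset_sample = as.integer(onset),
      duration = as.integer(phaseN),
      label = rep(c("eyes_closed", "eyes_open"), nCycles),
      stringsAsFactors = FALSE)
    new("Recording", data = data, sfreq = sfreq, labels = labels,
        events = events)
  })
}

#' Write subject parameters (or a cohort) to JSON
#'
#' @param params a \linkS4class{SubjectParams} or a list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSubjectParams <- function(params, path) {
  if (methods::is(params, "SubjectParams")) params <- list(params)
  lst <- lapply(params, function(p) {
    s <- methods::slotNames(p)
    stats::setNames(lapply(s, function(x) methods::slot(p, x)), s)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
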