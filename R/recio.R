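## Recording I/O and epoching. Continuous data interchange uses the European
## Data Format (EDF): ASCII header, 16-bit little-endian samples, 1-second
## data records, per-channel physical scaling from the data range. Events
## travel in a sidecar TSV because EDF annotation dialects vary. The true
## sample count is stored in the header's reserved field ("NS=<n>") so that
## zero-padding of the last record round-trips exactly.

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param labels channel labels (defaults to rownames of \code{data}).
#' @param events data.frame with columns \code{onset_sample} (0-based),
#'   \code{duration}, \code{label}; may be empty.
#' @return a \linkS4class{Recording}.
#' @export
newRecording <- function(data, sfreq, labels = rownames(data),
                         events = NULL) {
  if (is.null(events))
    events <- data.frame(onset_sample = integer(), duration = integer(),
                         label = character(), stringsAsFactors = FALSE)
  new("Recording", data = data, sfreq = sfreq, labels = as.character(labels),
      events = events)
}

.padField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too wide: ", s)
  formatC(s, width = -width)
}

.numField <- function(x, width) {
  for (d in seq(7, 1)) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) return(.padField(s, width))
  }
  stop("cannot format ", x, " into ", width, " bytes")
}

#' Write a recording to EDF (+ events sidecar TSV)
#'
#' Samples are quantized to 16 bits with the physical range set per channel
#' from the data minimum/maximum; the round-trip error is at most one
#' quantization step. Events are written to \code{<path>.events.tsv}.
#'
#' @param recording a \linkS4class{Recording}.
#' @param path output EDF path.
#' @return the path, invisibly.
#' @export
writeEDF <- function(recording, path) {
  data <- recording@data
  ns <- nrow(data)
  if (ns == 0) stop("cannot write a recording with no channels")
  n <- ncol(data)
  sfreq <- recording@sfreq
  spr <- round(sfreq)             # 1-second records
  if (abs(spr - sfreq) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  nrec <- ceiling(n / spr)

  physMin <- apply(data, 1, min)
  physMax <- apply(data, 1, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.padField("0", 8))
  wr(.padField("X X X X", 80))
  wr(.padField("Startdate X X X X", 80))
  wr(.padField("01.01.00", 8))
  wr(.padField("00.00.00", 8))
  wr(.padField(256 * (ns + 1), 8))
  wr(.padField(paste0("NS=", n), 44))
  wr(.padField(nrec, 8))
  wr(.padField(1, 8))
  wr(.padField(ns, 4))
  wr(paste0(vapply(recording@labels, .padField, "", width = 16),
            collapse = ""))
  wr(strrep(" ", 80 * ns))                       # transducer
  wr(strrep(paste0("uV", strrep(" ", 6)), ns))   # dimension
  wr(paste0(vapply(physMin, .numField, "", width = 8), collapse = ""))
  wr(paste0(vapply(physMax, .numField, "", width = 8), collapse = ""))
  wr(strrep(.padField(digMin, 8), ns))
  wr(strrep(.padField(digMax, 8), ns))
  wr(strrep(" ", 80 * ns))                       # prefiltering
  wr(strrep(.padField(spr, 8), ns))
  wr(strrep(" ", 32 * ns))                       # per-signal reserved

  ## digital conversion, pad last record with the physical-zero code
  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((data - physMin) * scale + digMin)
  dig <- pmin(pmax(dig, digMin), digMax)
  pad <- nrec * spr - n
  if (pad > 0) {
    zero <- round((0 - physMin) * scale + digMin)
    zero <- pmin(pmax(zero, digMin), digMax)
    dig <- cbind(dig, matrix(zero, ns, pad))
  }
  dim(dig) <- c(ns, spr, nrec)
  writeBin(as.integer(aperm(dig, c(2, 1, 3))), con, size = 2,
           endian = "little")
  writeEvents(recording@events, paste0(path, ".events.tsv"))
  invisible(path)
}

#' Read a recording from EDF
#'
#' Reads EDF files written by [writeEDF()] (and plain continuous EDF in
#' general). If \code{<path>.events.tsv} exists, events are attached.
#'
#' @param path EDF file path.
#' @return a \linkS4class{Recording}.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  fieldNum <- function(s, what, offset) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (!length(v) || is.na(v))
      stop("malformed EDF header: bad ", what, " at byte offset ", offset)
    v
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- fieldNum(rd(8), "header size", 184)
  reserved <- rd(44)
  nrec <- fieldNum(rd(8), "record count", 236)
  recDur <- fieldNum(rd(8), "record duration", 244)
  ns <- fieldNum(rd(4), "signal count", 252)
  if (ns < 1) stop("malformed EDF header: no signals (byte offset 252)")
  if (hdrBytes != 256 * (ns + 1))
    stop("malformed EDF header: header size mismatch at byte offset 184")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  physMin <- vapply(seq_len(ns), function(i)
    fieldNum(rd(8), "physical minimum", 256 + ns * 104 + (i - 1) * 8), 0)
  physMax <- vapply(seq_len(ns), function(i)
    fieldNum(rd(8), "physical maximum", 256 + ns * 112 + (i - 1) * 8), 0)
  digMin <- vapply(seq_len(ns), function(i) fieldNum(rd(8), "digital min", NA), 0)
  digMax <- vapply(seq_len(ns), function(i) fieldNum(rd(8), "digital max", NA), 0)
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) fieldNum(rd(8), "samples/record", NA), 0)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mismatched per-channel record lengths are not supported")
  spr <- spr[1]
  sfreq <- spr / recDur
  raw <- readBin(con, "integer", n = nrec * spr * ns, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) != nrec * spr * ns)
    stop("malformed EDF: truncated data records at byte offset ",
         256 * (ns + 1) + 2 * length(raw))
  dim(raw) <- c(spr, ns, nrec)
  dig <- aperm(raw, c(2, 1, 3))
  dim(dig) <- c(ns, spr * nrec)
  data <- (dig - digMin) / (digMax - digMin) * (physMax - physMin) + physMin
  nTrue <- sub("^NS=([0-9]+).*$", "\\1", trimws(reserved))
  if (grepl("^[0-9]+$", nTrue)) {
    nTrue <- as.integer(nTrue)
    if (nTrue <= ncol(data)) data <- data[, seq_len(nTrue), drop = FALSE]
  }
  evPath <- paste0(path, ".events.tsv")
  events <- if (file.exists(evPath)) readEvents(evPath) else NULL
  newRecording(data, sfreq, labels, events)
}

#' Read / write an event table TSV
#'
#' Tab-separated columns \code{onset_sample} (0-based), \code{duration}
#' (samples), \code{label}.
#'
#' @param path file path.
#' @return [readEvents()] returns the event data.frame.
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "duration", "label")
  if (!all(need %in% names(ev)))
    stop("event file must have columns onset_sample, duration, label")
  ev <- ev[, need]
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$duration <- as.integer(ev$duration)
  ev
}

#' @param events event data.frame to write.
#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Append a bipolar derivation to a recording
#'
#' Creates the channel \code{anode - cathode} and appends it; the original
#' channels are retained. The vertical and horizontal EOG derivations of the
#' recording montage are \code{Fp2 - EOGvu} and \code{F10 - F9}.
#'
#' @param recording a \linkS4class{Recording}.
#' @param anode,cathode channel labels.
#' @param newLabel label of the derived channel.
#' @return the recording with one channel appended.
#' @examples
#' rec <- newRecording(matrix(rnorm(20), 2, dimnames = list(c("a", "b"))), 10)
#' makeBipolar(rec, "a", "b", "a-b")
#' @export
makeBipolar <- function(recording, anode, cathode, newLabel) {
  miss <- setdiff(c(anode, cathode), recording@labels)
  if (length(miss))
    stop("channel(s) not present: ", paste(miss, collapse = ", "))
  d <- recording@data[match(anode, recording@labels), ] -
       recording@data[match(cathode, recording@labels), ]
  newRecording(rbind(recording@data, d), recording@sfreq,
               c(recording@labels, newLabel), recording@events)
}

#' Add the standard bipolar EOG channels
#'
#' Convenience wrapper adding \code{EOGv = Fp2 - EOGvu} (vertical) and
#' \code{EOGh = F10 - F9} (horizontal).
#'
#' @param recording a \linkS4class{Recording} containing Fp2, EOGvu, F9, F10.
#' @return the recording with channels \code{EOGv}, \code{EOGh} appended.
#' @export
addBipolarEOG <- function(recording) {
  recording <- makeBipolar(recording, "Fp2", "EOGvu", "EOGv")
  makeBipolar(recording, "F10", "F9", "EOGh")
}

#' Cut epochs around cue onsets
#'
#' Cuts one epoch per retained cue event, aligned so that the sample at
#' t = 0 is the cue-onset sample. The window is half-open
#' \code{[windowMs[1], windowMs[2])}: the sample at the left edge is included,
#' the sample at the right edge excluded, giving an unambiguous epoch length
#' (2800 samples for the default window at 1000 Hz).
#'
#' @param recording a \linkS4class{Recording}.
#' @param trials trial table with one row per cue event (in event order).
#' @param windowMs numeric length-2 window in ms relative to cue onset
#'   (default \code{c(-800, 2000)}).
#' @param cueLabel event label marking cue onsets (default \code{"cue"}).
#' @param latencyFilter keep only trials whose \code{target_latency_ms}
#'   equals this value (default 2000, the subset used for decoding); NULL
#'   keeps all trials.
#' @return an \linkS4class{EpochSet} whose trial table holds the retained
#'   rows of \code{trials}.
#' @export
epochRecording <- function(recording, trials, windowMs = c(-800, 2000),
                           cueLabel = "cue", latencyFilter = 2000) {
  if (diff(windowMs) <= 0)
    stop("epoch window must have positive length")
  ev <- recording@events
  cues <- ev$onset_sample[ev$label == cueLabel]
  if (length(cues) != nrow(trials))
    stop("found ", length(cues), " '", cueLabel, "' events for ",
         nrow(trials), " trials")
  keep <- if (is.null(latencyFilter)) rep(TRUE, nrow(trials))
          else trials$target_latency_ms == latencyFilter
  cues <- cues[keep]
  trials <- trials[keep, , drop = FALSE]
  sfreq <- recording@sfreq
  i0 <- round(windowMs[1] * sfreq / 1000)
  i1 <- round(windowMs[2] * sfreq / 1000) - 1
  nS <- ncol(recording@data)
  bad <- which(cues + i0 < 0 | cues + i1 >= nS)
  if (length(bad))
    stop("epoch window exceeds recording bounds for trial id(s): ",
         paste(trials$trial_id[bad], collapse = ", "))
  nT <- length(cues)
  nC <- nrow(recording@data)
  nW <- i1 - i0 + 1
  arr <- array(0, c(nT, nC, nW))
  for (k in seq_len(nT))
    arr[k, , ] <- recording@data[, cues[k] + (i0:i1) + 1L]
  new("EpochSet", data = arr, times = (i0:i1) * 1000 / sfreq, sfreq = sfreq,
      labels = recording@labels, trials = trials)
}

#' Select (and reorder) channels
#'
#' @param x a \linkS4class{Recording} or \linkS4class{EpochSet}.
#' @param labels channel labels to keep, in the requested order.
#' @return object of the same class restricted to \code{labels}.
#' @export
setGeneric("selectChannels", function(x, labels)
  standardGeneric("selectChannels"))

#' @rdname selectChannels
setMethod("selectChannels", "Recording", function(x, labels) {
  idx <- match(labels, x@labels)
  if (anyNA(idx))
    stop("channel(s) not present: ",
         paste(labels[is.na(idx)], collapse = ", "))
  newRecording(x@data[idx, , drop = FALSE], x@sfreq, labels, x@events)
})

#' @rdname selectChannels
setMethod("selectChannels", "EpochSet", function(x, labels) {
  idx <- match(labels, x@labels)
  if (anyNA(idx))
    stop("channel(s) not present: ",
         paste(labels[is.na(idx)], collapse = ", "))
  new("EpochSet", data = x@data[, idx, , drop = FALSE], times = x@times,
      sfreq = x@sfreq, labels = labels, trials = x@trials)
})
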