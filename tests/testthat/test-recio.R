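test_that("EDF round trip preserves data to quantization and events exactly", {
  t <- seq(0.01, 10, by = 0.01)
  d <- rbind(50 * sin(2 * pi * 3 * t), 20 * cos(2 * pi * 7 * t) + 5)
  ev <- data.frame(onset_sample = c(10L, 500L), duration = 0L,
                   label = c("cue", "target"), stringsAsFactors = FALSE)
  rec <- newRecording(d, 100, c("a", "b"), ev)
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  r2 <- readEDF(f)
  qstep <- max((apply(d, 1, max) - apply(d, 1, min)) / 65535)
  expect_lte(max(abs(signalData(r2) - d)), qstep)
  expect_identical(eventTable(r2), ev)
  expect_identical(channelLabels(r2), c("a", "b"))
  expect_equal(samplingRate(r2), 100)
  expect_equal(ncol(signalData(r2)), ncol(d))   # padding trimmed
})

test_that("a full synthetic session round-trips through EDF", {
  s <- fxSession()
  f <- tempfile(fileext = ".edf")
  writeEDF(s$rec, f)
  r2 <- readEDF(f)
  expect_identical(eventTable(r2), eventTable(s$rec))
  rng <- apply(signalData(s$rec), 1, function(x) diff(range(x)))
  expect_lte(max(abs(signalData(r2) - signalData(s$rec))),
             max(rng) / 65535)
})

test_that("EDF reader and writer reject malformed input", {
  expect_error(writeEDF(newRecording(matrix(0, 0, 10), 10, character()),
                        tempfile()), "no channels")
  bad <- tempfile(fileext = ".edf")
  writeLines("this is not an EDF header at all", bad)
  expect_error(readEDF(bad), "byte offset")
  expect_error(readEDF(tempfile()), "not found")
})

test_that("bipolar derivations subtract channels and keep the originals", {
  d <- matrix(rnorm(40), 4, 10,
              dimnames = list(c("Fp2", "EOGvu", "F9", "F10"), NULL))
  rec <- newRecording(d, 10)
  b <- makeBipolar(rec, "Fp2", "Fp2", "zero")
  expect_equal(signalData(b)["zero" == channelLabels(b), ], rep(0, 10))
  expect_equal(nrow(signalData(b)), 5)
  expect_error(makeBipolar(rec, "Fp2", "Oz", "x"), "Oz")

  ## symmetric signal cancels in the horizontal derivation
  d["F9", ] <- d["F10", ]
  rec <- newRecording(d, 10)
  eog <- addBipolarEOG(rec)
  expect_equal(signalData(eog)[channelLabels(eog) == "EOGh", ], rep(0, 10))

  ## injected blink recovered exactly by the vertical derivation
  blink <- exp(-((1:10 - 5) / 2)^2)
  baseDiff <- d["Fp2", ] - d["EOGvu", ]
  d["Fp2", ] <- d["Fp2", ] + blink
  d["EOGvu", ] <- d["EOGvu", ] - 0.3 * blink
  eog <- addBipolarEOG(newRecording(d, 10))
  v <- signalData(eog)[channelLabels(eog) == "EOGv", ]
  expect_equal(v - baseDiff, 1.3 * blink)
})

test_that("epoching keeps the 2000 ms-latency subset and preserves content", {
  big <- fxBigSession()
  ep <- epochRecording(big$rec, big$trials)
  expect_equal(dim(signalData(ep))[1], 300)   # 600 trials, half at 2000 ms
  expect_true(all(trialInfo(ep)$target_latency_ms == 2000))
  ## half-open window: [-800, 2000) at 64 Hz
  expect_equal(dim(signalData(ep))[3],
               round(2000 * 64 / 1000) - round(-800 * 64 / 1000))
  expect_equal(epochTimes(ep)[which(epochTimes(ep) == 0)], 0)

  ## content preservation against a direct slice
  ev <- eventTable(big$rec)
  cues <- ev$onset_sample[ev$label == "cue"]
  cues <- cues[big$trials$target_latency_ms == 2000]
  i0 <- round(-800 * 64 / 1000); i1 <- round(2000 * 64 / 1000) - 1
  expect_identical(signalData(ep)[7, , ],
                   signalData(big$rec)[, cues[7] + (i0:i1) + 1])

  expect_error(epochRecording(big$rec, big$trials, windowMs = c(0, 0)),
               "positive length")
  expect_error(
    epochRecording(big$rec, big$trials, windowMs = c(-5000, 2000),
                   latencyFilter = NULL),
    "trial id")
})

test_that("channel selection reorders consistently", {
  ep <- fxEpochs()
  sub <- selectChannels(ep, c("O2", "PO3"))
  expect_identical(channelLabels(sub), c("O2", "PO3"))
  expect_equal(signalData(sub)[, 2, ],
               signalData(ep)[, match("PO3", channelLabels(ep)), ])
  expect_error(selectChannels(ep, "NOPE"), "NOPE")
  ## selecting then computing = computing then selecting
  f1 <- welchBandpower(selectChannels(ep, c("Oz", "O1")))
  f2 <- welchBandpower(selectChannels(ep, c("O1", "Oz")))
  expect_equal(signalData(f1)[, 1], signalData(f2)[, 2])
})

test_that("event tables round-trip through TSV", {
  ev <- data.frame(onset_sample = c(3L, 9L), duration = c(0L, 5L),
                   label = c("cue", "eyes_closed"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeEvents(ev, f)
  expect_identical(readEvents(f), ev)
})
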