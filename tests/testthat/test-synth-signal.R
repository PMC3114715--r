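test_that("montage geometry is sane", {
  m <- fxMontage()
  expect_equal(nrow(m), 64)
  expect_true(all(c(scalpLabels(), "EOGvu") %in% m$label))
  xyz <- montagePositions(m)
  expect_equal(unname(sqrt(rowSums(xyz^2))), rep(1, 64))
  ## topology spot checks: Cz at vertex, Oz posterior, odd left / even right
  expect_equal(m$theta_deg[m$label == "Cz"], 0)
  expect_lt(xyz["Oz", 2], 0)
  expect_lt(xyz["PO3", 1], 0)
  expect_gt(xyz["PO4", 1], 0)
  ## round trip through TSV
  f <- tempfile(fileext = ".tsv")
  writeMontage(m, f)
  expect_equal(readMontage(f)$label, m$label)
})

test_that("session event markers exactly reproduce the trial table", {
  s <- fxSession()
  ev <- eventTable(s$rec)
  expect_equal(sum(ev$label == "cue"), nrow(s$trials))
  expect_equal(sum(ev$label == "target"), nrow(s$trials))
  expect_false(is.unsorted(ev$onset_sample))
  cues <- ev$onset_sample[ev$label == "cue"]
  targ <- ev$onset_sample[ev$label == "target"]
  expect_equal(targ - cues,
               round(s$trials$target_latency_ms * 64 / 1000))
})

test_that("session generation is deterministic and validates the montage", {
  s <- fxSession()
  again <- generateSession(s$params, s$trials, fxMontage(), sfreq = 64)
  expect_identical(signalData(again), signalData(s$rec))
  expect_error(
    generateSession(s$params, s$trials, fxMontage()[-5, ], sfreq = 64),
    fxMontage()$label[5])
})

test_that("no channel's alpha power depends on direction when kappa = 0", {
  p <- subjectParams("null", effectKappa = 0, eogConfound = 0, seed = 404L)
  tt <- generateTrialTable(nTrials = 200, seed = 404L)
  rec <- generateSession(p, tt, fxMontage(), sfreq = 64)
  ep <- selectChannels(epochRecording(rec, tt), posteriorElectrodes())
  fm <- welchBandpower(ep)
  ## permutation test on the ANOVA F statistic of summed posterior power
  pow <- rowSums(signalData(fm))
  fstat <- function(y, g) summary(stats::aov(y ~ factor(g)))[[1]]$F[1]
  obs <- fstat(pow, trialInfo(fm))
  set.seed(1)
  perm <- replicate(299, fstat(pow, sample(trialInfo(fm))))
  expect_gt(mean(perm >= obs), 0.01)
})

test_that("ocular deflections couple to direction through eogConfound", {
  s <- fxSession()   # eogConfound = 0.3
  rec <- selectChannels(s$rec, c("Fp2", "EOGvu", "F10", "F9"))
  rec <- selectChannels(addBipolarEOG(rec), c("EOGv", "EOGh"))
  ep <- epochRecording(rec, s$trials, windowMs = c(0, 2000),
                       latencyFilter = NULL)
  late <- epochTimes(ep) > 1000
  h <- apply(signalData(ep)[, 2, late], 1, mean)
  expected <- sin(directionAngle(s$trials$direction) * pi / 180)
  expect_gt(cor(h, expected), 0.5)

  p0 <- subjectParams("noeog", eogConfound = 0, seed = s$params@seed)
  rec0 <- generateSession(p0, s$trials, fxMontage(), sfreq = 64)
  rec0 <- selectChannels(rec0, c("Fp2", "EOGvu", "F10", "F9"))
  rec0 <- selectChannels(addBipolarEOG(rec0), c("EOGv", "EOGh"))
  ep0 <- epochRecording(rec0, s$trials, windowMs = c(0, 2000),
                        latencyFilter = NULL)
  h0 <- apply(signalData(ep0)[, 2, late], 1, mean)
  expect_lt(abs(cor(h0, expected)), 0.3)
})

test_that("resting recording has exact 15 s phases and eyes-closed alpha", {
  p <- subjectParams("r", alphaAmp = 5, seed = 31L)
  r <- generateResting(p, sfreq = 128, nCycles = 3)
  ev <- eventTable(r)
  expect_equal(nrow(ev), 6)
  expect_equal(unique(ev$duration), 15L * 128L)
  expect_equal(ev$label, rep(c("eyes_closed", "eyes_open"), 3))
  ## default configuration lasts about 6 minutes
  rFull <- generateResting(subjectParams(seed = 1), sfreq = 64)
  expect_equal(round(ncol(signalData(rFull)) / 64 / 60), 6)

  ## eyes-closed alpha strictly larger than eyes-open at POz
  psC <- covertAlpha:::.restingPsd(selectChannels(r, "POz"))
  psO <- covertAlpha:::.restingPsd(selectChannels(r, "POz"),
                                   phaseLabel = "eyes_open")
  sel <- psC$freq >= 8 & psC$freq <= 12
  expect_gt(max(psC$psd[sel, 1]), max(psO$psd[sel, 1]))

  ## amplitude -> power square law (diluted slightly by background)
  p2 <- subjectParams("r", alphaAmp = 10, seed = 31L)
  r2 <- generateResting(p2, sfreq = 128, nCycles = 3)
  a1 <- alphaPeak(r, "POz", basis = fxBasis())
  a2 <- alphaPeak(r2, "POz", basis = fxBasis())
  expect_equal(a2$peakPower / a1$peakPower, 4, tolerance = 0.2)
  ## determinism
  expect_identical(signalData(generateResting(p, sfreq = 128, nCycles = 3)),
                   signalData(r))
})

test_that("subject parameters validate their invariants", {
  expect_error(subjectParams(alphaAmp = -1), "alphaAmp")
  expect_error(subjectParams(effectKappa = -0.1), "effectKappa")
  expect_error(subjectParams(hemiAsym = 1.5), "hemiAsym")
  expect_error(subjectParams(rtGeoValid = 900, rtGeoInvalid = 800),
               "rtGeoInvalid")
  f <- tempfile(fileext = ".json")
  writeSubjectParams(generateCohort(3, seed = 1), f)
  js <- jsonlite::read_json(f)
  expect_equal(length(js), 3)
  expect_equal(js[[1]]$subjectId, "sub01")
})
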