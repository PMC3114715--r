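test_that("behavioral statistics recover the validity effect", {
  cohort <- generateCohort(8, seed = 77)
  tabs <- lapply(cohort, function(p)
    generateBehavior(generateTrialTable(seed = p@seed), p))
  bs <- behavioralStats(tabs)
  expect_equal(nrow(bs$perSubject), 8)
  expect_true(all(bs$perSubject$rt_geo_valid < bs$perSubject$rt_geo_invalid))
  expect_gt(bs$rtTest$t, 0)
  expect_lt(bs$rtTest$p, 0.01)
  expect_equal(bs$meanGeoValid, 719, tolerance = 0.05)
  expect_equal(bs$meanGeoInvalid, 881, tolerance = 0.05)
  ## the latency-filtered variant keeps only the decoding subset
  bs2 <- behavioralStats(tabs, latencyFilter = 2000)
  expect_lt(bs2$rtTest$p, 0.01)
  expect_true(all(abs(bs2$perSubject$accuracy - 0.87) < 0.1))
})

test_that("degenerate behavioral inputs are handled", {
  tt <- generateTrialTable(nTrials = 100, seed = 1)
  tt$rt_ms <- 700
  tt$correct <- TRUE
  tt$response_symbol <- tt$target_symbol
  bs <- behavioralStats(list(tt, tt))
  expect_equal(bs$rtTest$t, 0)
  expect_equal(bs$rtTest$p, 1)
  ## geometric mean closed form
  expect_equal(exp(mean(log(c(100, 10000)))), 1000)
  tt$rt_ms[1] <- -5
  expect_error(behavioralStats(list(tt)), "non-positive")
})

test_that("signed r^2 matches the point-biserial closed form", {
  ## toy: class A = {1, 2}, class B = {3, 4}
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  right <- c(FALSE, FALSE, TRUE, TRUE)
  r <- cor(c(1, 2, 3, 4), as.numeric(right))
  out <- signedR2Map(X, right)
  expect_equal(out$sgn_r2, sign(r) * r^2)
  ## equal class means -> 0
  X2 <- matrix(c(1, 3, 1, 3), ncol = 1)
  expect_equal(signedR2Map(X2, right)$sgn_r2, 0)
  ## perfectly separated -> +/- 1
  X3 <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_equal(signedR2Map(X3, right)$sgn_r2, 1)
  expect_equal(signedR2Map(X3, !right)$sgn_r2, -1)
  ## invariant under positive affine rescaling
  expect_equal(signedR2Map(1000 + 3 * X, right)$sgn_r2, out$sgn_r2)
  ## zero-variance electrode flagged, not propagated
  X4 <- cbind(X, 7)
  out4 <- signedR2Map(X4, right)
  expect_equal(out4$sgn_r2[2], 0)
  expect_true(out4$degenerate[2])
  expect_error(signedR2Map(X, rep(TRUE, 4)), "non-empty")
})

test_that("left-hemisphere power carries the right-vs-left contrast", {
  p <- subjectParams("lat", effectKappa = 2, hemiAsym = 0.5,
                     eogConfound = 0, seed = 55L)
  cs <- fxSubjectCsd(p, nTrials = 300)
  pool <- poolLeftRight(welchBandpower(selectChannels(cs,
                                                      posteriorElectrodes())))
  sr <- signedR2Map(pool$X, pool$right)
  sr$electrode <- posteriorElectrodes()
  left <- sr$sgn_r2[sr$electrode %in% hemisphereSubsets()$left]
  right <- sr$sgn_r2[sr$electrode %in% hemisphereSubsets()$right]
  expect_gt(mean(left), 0)
  expect_gt(mean(left), mean(right))
})

test_that("the peak ANOVA matches a hand-computed textbook example", {
  peaks <- data.frame(
    subject = rep(1:3, 3),
    subset = rep(c("left", "right", "both"), each = 3),
    peak = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  ## by hand: group means 2, 3, 7; SSB = 42 (df 2), SSW = 6 (df 6) -> F = 21
  a <- peakAnova(peaks)
  expect_equal(a$F, 21)
  expect_equal(a$df, c(2, 6))
  expect_equal(a$p, pf(21, 2, 6, lower.tail = FALSE))
  expect_equal(nrow(a$tukey), 3)
  ## identical groups -> F ~ 0, no significant contrasts
  peaks$peak <- rep(c(1, 2, 3), 3)
  a0 <- peakAnova(peaks)
  expect_lt(a0$F, 1e-10)
  expect_true(all(a0$tukey$p_adj > 0.99))
})

test_that("EOG confound classification dissociates from the EEG", {
  ## subject with ocular coupling but no cortical effect
  p1 <- subjectParams("eogonly", effectKappa = 0, eogConfound = 1,
                      seed = 8001L)
  tt1 <- generateTrialTable(nTrials = 200, seed = 8001L)
  rec1 <- generateSession(p1, tt1, fxMontage(), sfreq = 64)
  eo1 <- eogConfound(rec1, tt1, lambdaGrid = fxGrid(), seed = 81)
  ee1 <- allPairsAnalysis(
    csdTransform(selectChannels(epochRecording(rec1, tt1), scalpLabels()),
                 fxBasis()),
    lambdaGrid = fxGrid(), seed = 82)
  expect_equal(nrow(eo1$summary), 15)
  expect_gt(mean(eo1$summary$accuracy), 0.8)
  expect_lt(mean(ee1$summary$accuracy), 0.62)
  expect_gt(mean(eo1$summary$accuracy) - mean(ee1$summary$accuracy), 0.25)
  ## no EOG channels -> channel error
  expect_error(eogConfound(selectChannels(rec1, scalpLabels()), tt1),
               "EOGvu")
})

test_that("EOG accuracies at zero coupling sit at chance", {
  p0 <- subjectParams("noeog", effectKappa = 1.5, eogConfound = 0,
                      seed = 8002L)
  tt0 <- generateTrialTable(nTrials = 200, seed = 8002L)
  rec0 <- generateSession(p0, tt0, fxMontage(), sfreq = 64)
  eo0 <- eogConfound(rec0, tt0, lambdaGrid = fxGrid(), seed = 83)
  expect_lt(abs(mean(eo0$summary$accuracy) - 0.5), 0.06)
})

test_that("EEG-EOG accuracy correlation pools significant pairs", {
  mk <- function(acc, p) data.frame(pair_a = 1, pair_b = 2,
                                    accuracy = acc, p = p)
  eeg <- list(mk(c(0.9, 0.8, 0.7), c(0.01, 0.02, 0.5)),
              mk(c(0.6, 0.5), c(0.03, 0.9)))
  eog <- list(mk(c(0.45, 0.40, 0.35), c(0.9, 0.8, 0.01)),
              mk(c(0.30, 0.5), c(0.7, 0.9)))
  r <- eegEogAccuracyCorrelation(eeg, eog)
  expect_equal(r$n, 4)   # three from subject 1, one from subject 2
  ## perfectly correlated toy vectors give r = 1
  eog2 <- list(mk(2 * c(0.9, 0.8, 0.7) - 1, c(0.01, 0.01, 0.01)),
               mk(2 * c(0.6, 0.5) - 1, c(0.01, 0.9)))
  r2 <- eegEogAccuracyCorrelation(eeg, eog2)
  expect_equal(r2$r, 1)
})

test_that("hemisphere comparison returns per-subset peaks and an ANOVA", {
  p2 <- subjectParams("h2", effectKappa = 1, hemiAsym = 0.5,
                      eogConfound = 0, seed = 560L)
  epochsList <- list(fxCsd(), fxSubjectCsd(p2))
  hc <- hemisphereComparison(epochsList, seed = 5, lambdaGrid = fxGrid())
  expect_equal(nrow(hc$peaks), 6)
  expect_setequal(hc$peaks$subset, c("left", "right", "both"))
  expect_true(all(hc$peaks$peak >= 0.5))
  expect_true(is.finite(hc$F))
  expect_equal(nrow(hc$tukey), 3)
})
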