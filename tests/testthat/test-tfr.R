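# Epochs for TFR tests are built directly as arrays (sinusoids, noise) so
# every expectation has a closed-form or Monte-Carlo oracle.

test_that("a pure sinusoid concentrates amplitude at its own frequency", {
  sfreq <- 250
  t <- (0:999) / sfreq
  A <- 3
  arr <- array(rep(A * sin(2 * pi * 10 * t), each = 2), c(2, 1, 1000))
  ep <- fxEpochsFromArray(arr, sfreq)
  tf <- tfrAmplitude(morletTransform(ep, freqs = 4:30))
  prof <- apply(signalData(tf)[1, 1, , tf@valid[1, ]], 1, mean)
  expect_equal(tf@freqs[which.max(prof)], 10)
  ## stable over time at the peak row (valid region)
  row10 <- signalData(tf)[1, 1, 7, tf@valid[1, ]]
  expect_lt(stats::sd(row10) / mean(row10), 0.01)
  ## linear in amplitude
  tf2 <- tfrAmplitude(morletTransform(fxEpochsFromArray(2 * arr, sfreq),
                                      freqs = 4:30))
  expect_equal(signalData(tf2), 2 * signalData(tf))
})

test_that("wavelet support matches the printed half-width and is enforced", {
  sfreq <- 1000
  arr <- array(rnorm(2 * 2800), c(1, 2, 2800))
  ep <- fxEpochsFromArray(arr, sfreq, t0 = -800)
  tf <- morletTransform(ep, freqs = 4:30)
  ## half-support of the 4 Hz wavelet: k q / (2 pi f) = 417.8 ms
  expect_equal(max(tf@halfWidthMs), 3 * 3.5 / (2 * pi * 4) * 1000,
               tolerance = 0.005)
  expect_lt(max(tf@halfWidthMs), 419)
  ## validity mask marks edge-contaminated bins
  expect_false(tf@valid[1, 1])
  expect_true(tf@valid[1, which.min(abs(tf@times))])
  expect_error(morletTransform(ep, freqs = c(0, 10)), "> 0")
  short <- fxEpochsFromArray(array(rnorm(100), c(1, 1, 100)), 1000)
  expect_error(morletTransform(short, freqs = 4:30), "shorter than")
})

test_that("baseline correction zeroes stationary signals and finds steps", {
  sfreq <- 250
  t <- (-500:699) / sfreq    # -2000..2796 ms
  amp <- ifelse(t < 1.5, 1, 3)
  x <- amp * sin(2 * pi * 10 * t)
  arr <- array(rep(x, each = 2), c(2, 1, length(t)))
  ep <- fxEpochsFromArray(arr, sfreq, t0 = -2000)
  tf <- tfrAmplitude(morletTransform(ep, freqs = c(4, 10)))
  bc <- baselineCorrect(tf, windowMs = c(-1500, -500))
  pre <- bc@times > -400 & bc@times < 800
  post <- bc@times > 2000 & bc@times < 2400
  base <- mean(signalData(tf)[1, 1, 2, tf@times > -1500 & tf@times < -500])
  expect_equal(mean(signalData(bc)[1, 1, 2, pre]), 0,
               tolerance = 0.02 * base)
  expect_equal(mean(signalData(bc)[1, 1, 2, post]), 2 * base,
               tolerance = 0.05 * base)
  ## leakage guard: window end past -(half widest wavelet) fails hard
  expect_error(baselineCorrect(tf, windowMs = c(-800, -100)), "leak")
  expect_error(baselineCorrect(morletTransform(ep, freqs = c(4, 10))),
               "amplitude")
})

test_that("PLF is 1 for identical trials and ~0.886/sqrt(n) for random phase", {
  sfreq <- 250
  t <- (0:499) / sfreq
  arr <- array(rep(sin(2 * pi * 10 * t) + 0.3 * sin(2 * pi * 6 * t),
                   each = 8), c(8, 1, 500))
  cpx <- morletTransform(fxEpochsFromArray(arr, sfreq), freqs = c(6, 10))
  p1 <- plf(cpx)
  expect_equal(max(abs(signalData(p1)[1, , p1@valid[1, ]] - 1)), 0,
               tolerance = 1e-9)

  ## Monte-Carlo oracle on synthetic unit phasors: E|mean| = 0.886/sqrt(n)
  n <- 16
  set.seed(42)
  coeffs <- array(complex(modulus = 1,
                          argument = runif(n * 2000, 0, 2 * pi)),
                  c(n, 1, 1, 2000))
  tfr <- new("TFRResult", coeffs = coeffs, freqs = 10, times = 1:2000,
             labels = "x", mode = "complex",
             valid = matrix(TRUE, 1, 2000), halfWidthMs = 0, nExcluded = 0)
  vals <- signalData(plf(tfr))
  expect_equal(mean(vals), 0.886 / sqrt(n), tolerance = 0.02)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("PLF ignores per-trial amplitude scaling and excludes zeros", {
  set.seed(7)
  coeffs <- array(complex(real = rnorm(6 * 50), imaginary = rnorm(6 * 50)),
                  c(6, 1, 1, 50))
  mk <- function(co) new("TFRResult", coeffs = co, freqs = 10, times = 1:50,
                         labels = "x", mode = "complex",
                         valid = matrix(TRUE, 1, 50), halfWidthMs = 0,
                         nExcluded = 0)
  a <- signalData(plf(mk(coeffs)))
  scaled <- coeffs * rep(c(0.1, 5, 2, 9, 1, 3), times = 50)
  expect_equal(signalData(plf(mk(scaled))), a, tolerance = 1e-12)
  ## zero-magnitude coefficients are excluded with a count
  coeffs[1, 1, 1, 3] <- 0
  pz <- plf(mk(coeffs))
  expect_equal(pz@nExcluded, 1)
  co0 <- coeffs; co0[, 1, 1, 5] <- 0
  expect_true(is.na(signalData(plf(mk(co0)))[1, 1, 5]))
  expect_error(plf(mk(coeffs[1, , , , drop = FALSE])), "2 trials")
})

test_that("white noise gives a flat expected amplitude over time", {
  set.seed(9)
  arr <- array(rnorm(40 * 2 * 600), c(40, 2, 600))
  tf <- tfrAmplitude(morletTransform(fxEpochsFromArray(arr, 200),
                                     freqs = c(8, 12)))
  prof <- apply(signalData(tf)[, , 1, tf@valid[1, ]], 3, mean)
  expect_lt(stats::sd(prof) / mean(prof), 0.1)
})

test_that("amplitude averages are invariant to trial order", {
  ep <- fxEpochsFromArray(array(rnorm(5 * 2 * 400), c(5, 2, 400)), 200)
  tf <- tfrAmplitude(morletTransform(ep, freqs = c(10, 20)))
  perm <- c(4, 1, 5, 2, 3)
  epP <- fxEpochsFromArray(signalData(ep)[perm, , , drop = FALSE], 200)
  tfP <- tfrAmplitude(morletTransform(epP, freqs = c(10, 20)))
  expect_equal(apply(signalData(tfP), c(2, 3, 4), mean),
               apply(signalData(tf), c(2, 3, 4), mean))
})

test_that("only the cue transient is phase-locked in a synthetic session", {
  s <- fxSession()
  ep <- epochRecording(s$rec, s$trials)   # 100 epochs at 64 Hz
  cpx <- morletTransform(ep, freqs = c(5, 10, 11), channels = c("Oz", "POz"))
  pl <- plf(cpx)
  early <- pl@times >= 200 & pl@times <= 300
  late <- pl@times >= 1000 & pl@times <= 1900
  floorPlf <- 0.886 / sqrt(dim(signalData(cpx))[1])
  expect_gt(max(signalData(pl)[1, 1, early]), 0.7)
  expect_lt(mean(signalData(pl)[, 2:3, late]), 2 * floorPlf)
})
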