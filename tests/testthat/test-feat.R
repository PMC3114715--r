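test_that("Welch bandpower matches a hand-rolled oracle", {
  sfreq <- 64
  set.seed(11)
  arr <- array(rnorm(3 * 2 * 180), c(3, 2, 180))   # ~2800 ms epochs
  ep <- fxEpochsFromArray(arr, sfreq, t0 = -800)
  fm <- welchBandpower(ep)

  ## independent re-computation with an explicit loop
  sel <- which(ep@times >= 500 & ep@times < 2000)
  N <- length(sel)
  L <- floor(2 * N / 9)
  starts <- (0:7) * floor(L / 2)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  oracle <- function(x) {
    ps <- sapply(starts, function(s) {
      X <- Mod(fft(x[s + 1:L] * w))^2 / (sfreq * sum(w^2))
      X <- X[1:(floor(L / 2) + 1)]
      X[2:(length(X) - ifelse(L %% 2 == 0, 1, 0))] <-
        2 * X[2:(length(X) - ifelse(L %% 2 == 0, 1, 0))]
      X
    })
    freqs <- (0:floor(L / 2)) * sfreq / L
    mean(rowMeans(ps)[freqs >= 8 & freqs <= 12])
  }
  for (tr in 1:3) for (ch in 1:2)
    expect_equal(signalData(fm)[tr, ch], oracle(arr[tr, ch, sel]))
  ## exactly 8 segments fit for every tested window length
  for (N in c(1000, 1500, 3000)) {
    L <- floor(2 * N / 9)
    expect_lte(7 * floor(L / 2) + L, N)        # 8th segment fits
    expect_gt(8 * floor(L / 2) + L, N)         # a 9th would not
  }
})

test_that("a sinusoid's bandpower integrates to A^2/2", {
  ## window chosen so the 1 Hz bin grid puts 10 Hz and its taper sidebands
  ## inside the 8-12 Hz band
  sfreq <- 1000
  A <- 2.5
  t <- (0:4499) / sfreq
  arr <- array(rep(A * sin(2 * pi * 10 * t + 0.7), each = 1),
               c(1, 1, length(t)))
  ep <- fxEpochsFromArray(arr, sfreq)
  sel <- ep@times >= 0 & ep@times < 4500
  m <- matrix(arr[1, 1, sel], ncol = 1)
  ps <- covertAlpha:::.welchPsdMat(m, sfreq)
  band <- ps$freq >= 8 & ps$freq <= 12
  df <- diff(ps$freq)[1]
  expect_equal(sum(ps$psd[band, 1]) * df, A^2 / 2, tolerance = 0.05)
  ## untapered full-window periodogram oracle agrees
  P <- Mod(fft(arr[1, 1, sel]))^2 / (sfreq * length(t))
  fr <- (seq_along(P) - 1) * sfreq / length(P)
  expect_equal(2 * sum(P[fr >= 8 & fr <= 12]) * (sfreq / length(P)),
               A^2 / 2, tolerance = 0.05)
})

test_that("bandpower is exactly zero for zero signal and scales quadratically", {
  ep <- fxEpochsFromArray(array(0, c(2, 2, 180)), 64, t0 = -800)
  expect_true(all(signalData(welchBandpower(ep)) == 0))
  set.seed(3)
  arr <- array(rnorm(2 * 2 * 180), c(2, 2, 180))
  f1 <- welchBandpower(fxEpochsFromArray(arr, 64, t0 = -800))
  f3 <- welchBandpower(fxEpochsFromArray(3 * arr, 64, t0 = -800))
  expect_equal(signalData(f3), 9 * signalData(f1))
})

test_that("bandpower validates window and band", {
  ep <- fxEpochsFromArray(array(rnorm(360), c(1, 2, 180)), 64, t0 = -800)
  expect_error(welchBandpower(ep, bandHz = c(8, 50)), "Nyquist")
  expect_error(welchBandpower(ep, windowMs = c(500, 560)), "shorter")
})

test_that("features are invariant to trial order and electrode permutation", {
  ep <- fxEpochs()
  f <- welchBandpower(selectChannels(ep, c("Oz", "O1", "O2")))
  perm <- sample(nrow(signalData(f)))
  arr <- signalData(selectChannels(ep, c("O1", "Oz", "O2")))[perm, , ,
                                                             drop = FALSE]
  ep2 <- fxEpochsFromArray(arr, 64, labels = c("O1", "Oz", "O2"), t0 = -800,
                           trials = trialInfo(ep)[perm, ])
  ep2@times <- ep@times
  f2 <- welchBandpower(ep2)
  expect_equal(signalData(f2)[order(perm), c(2, 1, 3)], signalData(f))
})

test_that("pair features carry balanced labels and validate inputs", {
  big <- fxBigCsd()
  fm <- buildFeatures(big, pair = c(1, 4))
  expect_equal(nrow(signalData(fm)), 100)    # 50 + 50 in the 2000 ms subset
  expect_equal(ncol(signalData(fm)), 9)
  expect_identical(fm@electrodes, posteriorElectrodes())
  expect_setequal(unique(trialInfo(fm)), c(1L, 4L))
  expect_error(buildFeatures(big, pair = c(1, 1)), "distinct")
  expect_error(buildFeatures(big, electrodes = c("Oz", "XX"), pair = c(1, 2)),
               "XX")
  small <- welchBandpower(selectChannels(fxEpochs(), "Oz"))
  expect_error(featurePair(small, c(1, 2), minTrials = 100),
               "insufficient trials")
})
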