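# Shared fixtures, built lazily and cached for the whole test run. Simulation
# problem sizes are scaled (64 Hz sampling, 200-600 trials) so the suite
# exercises the full pipeline quickly; the design proportions are identical
# to the study-scale defaults.

.fx <- new.env(parent = emptyenv())

fxCache <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fxMontage <- function() fxCache("montage", defaultMontage())

fxScalpMontage <- function() fxCache("scalpMontage", {
  m <- fxMontage()
  m[match(scalpLabels(), m$label), ]
})

fxBasis <- function() fxCache("basis", buildSplineBasis(fxScalpMontage()))

# small lambda grid for Monte-Carlo-heavy tests (config-exposed parameter)
fxGrid <- function() 10^seq(-2, 2, by = 1)

# one strong subject, 200-trial session at 64 Hz
fxSession <- function() fxCache("session", {
  p <- subjectParams("fx1", effectKappa = 1.5, hemiAsym = 0.75,
                     eogConfound = 0.3, seed = 101L)
  tt <- generateTrialTable(nTrials = 200, seed = 101L)
  list(params = p, trials = tt,
       rec = generateSession(p, tt, fxMontage(), sfreq = 64))
})

fxEpochs <- function() fxCache("epochs", {
  s <- fxSession()
  epochRecording(s$rec, s$trials)
})

fxCsd <- function() fxCache("csd", {
  csdTransform(selectChannels(fxEpochs(), scalpLabels()), fxBasis())
})

# full 600-trial session (default design) at 64 Hz
fxBigSession <- function() fxCache("big", {
  p <- subjectParams("fx2", effectKappa = 1.5, hemiAsym = 0.75,
                     eogConfound = 0.3, seed = 202L)
  tt <- generateTrialTable(seed = 202L)
  list(params = p, trials = tt,
       rec = generateSession(p, tt, fxMontage(), sfreq = 64))
})

fxBigEpochs <- function() fxCache("bigEpochs", {
  s <- fxBigSession()
  epochRecording(s$rec, s$trials)
})

fxBigCsd <- function() fxCache("bigCsd", {
  csdTransform(selectChannels(fxBigEpochs(), scalpLabels()), fxBasis())
})

# helper: CSD-filtered epochs for an arbitrary subject at test scale
fxSubjectCsd <- function(params, nTrials = 200, sfreq = 64) {
  tt <- generateTrialTable(nTrials = nTrials, seed = params@seed)
  rec <- generateSession(params, tt, fxMontage(), sfreq = sfreq)
  csdTransform(selectChannels(epochRecording(rec, tt), scalpLabels()),
               fxBasis())
}

# build an EpochSet directly from a trials x channels x time array
fxEpochsFromArray <- function(arr, sfreq, labels = NULL, t0 = 0,
                              trials = NULL) {
  d <- dim(arr)
  if (is.null(labels)) labels <- paste0("ch", seq_len(d[2]))
  if (is.null(trials))
    trials <- data.frame(trial_id = seq_len(d[1]),
                         direction = rep_len(1:6, d[1]))
  new("EpochSet", data = arr, times = t0 + (seq_len(d[3]) - 1) * 1000 / sfreq,
      sfreq = sfreq, labels = labels, trials = trials)
}
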