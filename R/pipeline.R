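## End-to-end orchestration: simulate a cohort, preprocess, decode, and emit
## report tables. All randomness fans out from the subject seed (generator)
## and a derived CV seed, so stages can be rerun independently and a rerun
## with the same configuration is bit-identical.

#' Default run configuration
#'
#' Nested list of all module settings at study scale (64-channel montage,
#' 1000 Hz, 600 trials, 8 subjects). Override entries via [runConfig()];
#' unknown keys are rejected.
#'
#' @return named nested list.
#' @export
defaultRunConfig <- function() {
  list(
    synth = list(nTrials = 600L, validFrac = 0.8,
                 latencyMix = c("2000" = 0.5, "500" = 0.3),
                 sfreq = 1000, nSubjects = 8L, predictorSlope = 0.45,
                 predictorNoise = 0.1, hemiAsym = 0.3, eogConfound = 0.3,
                 restingCycles = 10L),
    epoch = list(windowMs = c(-800, 2000), latencyFilter = 2000),
    csd = list(m = 4, lambda = 1e-5, nTerms = 50),
    tfr = list(enabled = FALSE, freqs = 4:30, cycles = 3.5, truncK = 3,
               channels = c("PO3", "POz", "PO4", "Oz"), decim = 20L,
               baselineWindow = c(-800, -419), baselineMode = "subtract"),
    feat = list(windowMs = c(500, 2000), bandHz = c(8, 12), nSegments = 8,
                overlap = 0.5, electrodes = posteriorElectrodes(),
                minTrials = 10),
    clf = list(lambdaGrid = defaultLambdaGrid(), outerFolds = 10,
               innerFolds = 5),
    stats = list(hemisphere = TRUE, eog = TRUE),
    eog = list(windowMs = c(0, 2000), lowpassHz = 20,
               nSamplesPerChannel = 40),
    predictor = list(enabled = TRUE, pair = c("PO3", "PO4"), segSec = 2),
    seed = 1L)
}

.mergeConfig <- function(template, override, path = "") {
  if (!length(override)) return(template)
  nm <- names(override)
  unknown <- setdiff(nm, names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  for (k in nm) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      template[[k]] <- .mergeConfig(template[[k]], override[[k]],
                                    paste0(path, ".", k))
    else template[[k]] <- override[[k]]
  }
  template
}

#' Build a run configuration
#'
#' Starts from [defaultRunConfig()] and applies overrides; any key not in the
#' default schema raises an error.
#'
#' @param ... named overrides, e.g.
#'   \code{runConfig(synth = list(sfreq = 250), seed = 3)}.
#' @return validated configuration list.
#' @export
runConfig <- function(...) .mergeConfig(defaultRunConfig(), list(...))

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every report so
#' output tables can be traced to the configuration that produced them.
#'
#' @param config configuration list.
#' @return character MD5 digest.
#' @export
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

## CV seed derived from the subject seed, kept below 2^31
.cvSeed <- function(subjectSeed, offset = 0L)
  (as.integer(subjectSeed) %% 2000000L) + 7919L * (1L + as.integer(offset))

#' Run the full analysis for one subject
#'
#' Generates the subject's task session, behavior and (optionally) resting
#' recording; epochs the 2000 ms-latency trials; applies CSD; classifies all
#' fifteen direction pairs; and computes the hemisphere-subset peaks, the EOG
#' confound classification, the resting alpha index and (optionally) a
#' time-frequency summary. Deterministic given (params, config).
#'
#' @param params \linkS4class{SubjectParams}.
#' @param config configuration from [runConfig()].
#' @param montage electrode montage (default [defaultMontage()]).
#' @param basis optional precomputed scalp \linkS4class{SplineBasis} (built
#'   when NULL).
#' @param outDir optional directory for per-subject CSV/JSON artifacts.
#' @return list ("subject report") with elements \code{subjectId},
#'   \code{trials}, \code{pairSummary}, \code{peakAccuracy}, \code{bestPair},
#'   \code{hemiPeaks}, \code{eogSummary}, \code{alphaIndex}, \code{tfr},
#'   \code{configHash}.
#' @export
runSubject <- function(params, config = defaultRunConfig(),
                       montage = defaultMontage(), basis = NULL,
                       outDir = NULL) {
  sy <- config$synth
  trials <- generateTrialTable(sy$nTrials, sy$validFrac, sy$latencyMix,
                               seed = params@seed)
  trials <- generateBehavior(trials, params)
  session <- generateSession(params, trials, montage, sfreq = sy$sfreq)
  epochs <- epochRecording(session, trials,
                           windowMs = config$epoch$windowMs,
                           latencyFilter = config$epoch$latencyFilter)
  scalp <- selectChannels(epochs, scalpLabels())
  if (is.null(basis))
    basis <- buildSplineBasis(montage[match(scalpLabels(), montage$label), ],
                              m = config$csd$m, lambda = config$csd$lambda,
                              nTerms = config$csd$nTerms)
  csdE <- csdTransform(scalp, basis)

  cl <- config$clf
  ft <- config$feat
  runPairs <- function(electrodes, seedOffset)
    allPairsAnalysis(csdE, electrodes = electrodes,
                     lambdaGrid = cl$lambdaGrid, outerFolds = cl$outerFolds,
                     innerFolds = cl$innerFolds, windowMs = ft$windowMs,
                     bandHz = ft$bandHz, nSegments = ft$nSegments,
                     overlap = ft$overlap, minTrials = ft$minTrials,
                     seed = .cvSeed(params@seed, seedOffset))
  eeg <- runPairs(ft$electrodes, 0L)

  hemiPeaks <- NULL
  if (isTRUE(config$stats$hemisphere)) {
    hs <- hemisphereSubsets()
    hemiPeaks <- data.frame(
      subset = names(hs),
      peak = vapply(seq_along(hs), function(i)
        if (identical(hs[[i]], ft$electrodes)) eeg$peakAccuracy
        else runPairs(hs[[i]], i)$peakAccuracy, 0))
  }

  eogSummary <- NULL
  if (isTRUE(config$stats$eog)) {
    eo <- config$eog
    eogSummary <- eogConfound(session, trials, windowMs = eo$windowMs,
                              lowpassHz = eo$lowpassHz,
                              nSamplesPerChannel = eo$nSamplesPerChannel,
                              latencyFilter = config$epoch$latencyFilter,
                              lambdaGrid = cl$lambdaGrid,
                              outerFolds = cl$outerFolds,
                              innerFolds = cl$innerFolds,
                              minTrials = ft$minTrials,
                              seed = .cvSeed(params@seed, 99L))$summary
  }

  ai <- NULL
  if (isTRUE(config$predictor$enabled)) {
    resting <- generateResting(params, sfreq = sy$sfreq,
                               nCycles = sy$restingCycles,
                               montage = montage)
    ai <- alphaIndex(resting, pair = config$predictor$pair, basis = basis,
                     montage = montage, segSec = config$predictor$segSec)
  }

  tfrSummary <- NULL
  if (isTRUE(config$tfr$enabled)) {
    tf <- config$tfr
    cpx <- morletTransform(csdE, freqs = tf$freqs, cycles = tf$cycles,
                           truncK = tf$truncK, channels = tf$channels,
                           decim = tf$decim)
    amp <- baselineCorrect(tfrAmplitude(cpx), tf$baselineWindow,
                           tf$baselineMode)
    tfrSummary <- list(
      amplitude = apply(amp@coeffs, c(2, 3, 4), mean),
      plf = plf(cpx)@coeffs,
      freqs = amp@freqs, times = amp@times, channels = amp@labels)
  }

  report <- list(subjectId = params@subjectId, trials = trials,
                 pairSummary = eeg$summary, peakAccuracy = eeg$peakAccuracy,
                 bestPair = eeg$bestPair, hemiPeaks = hemiPeaks,
                 eogSummary = eogSummary, alphaIndex = ai, tfr = tfrSummary,
                 configHash = configHash(config))
  if (!is.null(outDir)) .writeSubjectReport(report, outDir)
  report
}

.writeSubjectReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(outDir, report$subjectId)
  writeCsv <- function(df, path) {
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", report$configHash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  writeCsv(report$pairSummary, paste0(stem, "_pairs.csv"))
  writeCsv(report$trials, paste0(stem, "_trials.csv"))
  if (!is.null(report$hemiPeaks))
    writeCsv(report$hemiPeaks, paste0(stem, "_hemisphere.csv"))
  if (!is.null(report$eogSummary))
    writeCsv(report$eogSummary, paste0(stem, "_eog.csv"))
  js <- list(subject_id = report$subjectId, config_hash = report$configHash,
             peak_accuracy = report$peakAccuracy,
             best_pair = report$bestPair,
             alpha_index = report$alphaIndex$pooledPower)
  jsonlite::write_json(js, paste0(stem, "_report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Run the full cohort analysis
#'
#' Simulates (or accepts) a cohort of subjects, runs [runSubject()] for each,
#' and aggregates: behavioral paired t-tests, hemisphere-subset ANOVA with
#' Tukey-Kramer contrasts, the resting-alpha predictor correlation, and the
#' EEG-EOG accuracy correlation over significant pairs.
#'
#' @param config configuration from [runConfig()]; \code{config$seed} seeds
#'   the cohort and \code{config$synth$nSubjects} sets its size.
#' @param cohort optional list of \linkS4class{SubjectParams}; generated with
#'   [generateCohort()] when NULL.
#' @param montage electrode montage.
#' @param outDir optional output directory; per-subject artifacts plus
#'   cohort-level CSV/JSON tables and a reproducibility manifest are written.
#' @return list ("cohort report") with \code{subjects} (per-subject reports),
#'   \code{behavior}, \code{behavior2000}, \code{hemisphere},
#'   \code{predictor}, \code{eegEog}, \code{peaks}, \code{manifest}.
#' @export
runCohort <- function(config = defaultRunConfig(), cohort = NULL,
                      montage = defaultMontage(), outDir = NULL) {
  sy <- config$synth
  if (is.null(cohort))
    cohort <- generateCohort(sy$nSubjects,
                             predictorSlope = sy$predictorSlope,
                             predictorNoise = sy$predictorNoise,
                             seed = config$seed, hemiAsym = sy$hemiAsym,
                             eogConfound = sy$eogConfound)
  if (length(cohort) < 3) stop("a cohort needs at least 3 subjects")
  basis <- buildSplineBasis(montage[match(scalpLabels(), montage$label), ],
                            m = config$csd$m, lambda = config$csd$lambda,
                            nTerms = config$csd$nTerms)
  reports <- lapply(cohort, runSubject, config = config, montage = montage,
                    basis = basis,
                    outDir = if (is.null(outDir)) NULL
                             else file.path(outDir, "subjects"))

  trialsList <- lapply(reports, `[[`, "trials")
  behavior <- behavioralStats(trialsList)
  behavior2000 <- behavioralStats(trialsList,
                                  latencyFilter = config$epoch$latencyFilter)

  peaks <- data.frame(
    subject = vapply(reports, `[[`, "", "subjectId"),
    peak = vapply(reports, `[[`, 0, "peakAccuracy"))

  hemisphere <- NULL
  if (isTRUE(config$stats$hemisphere)) {
    hp <- do.call(rbind, lapply(seq_along(reports), function(i)
      cbind(subject = i, reports[[i]]$hemiPeaks)))
    hemisphere <- c(list(peaks = hp), peakAnova(hp))
  }

  predictor <- NULL
  if (isTRUE(config$predictor$enabled)) {
    idx <- vapply(reports, function(r) r$alphaIndex$pooledPower, 0)
    predictor <- c(correlatePredictor(idx, peaks$peak),
                   list(indices = idx))
  }

  eegEog <- NULL
  if (isTRUE(config$stats$eog))
    eegEog <- eegEogAccuracyCorrelation(
      lapply(reports, `[[`, "pairSummary"),
      lapply(reports, `[[`, "eogSummary"))

  manifest <- list(config = config, config_hash = configHash(config),
                   seed = config$seed,
                   subject_seeds = vapply(cohort, function(p) p@seed, 0L),
                   package_version =
                     as.character(utils::packageVersion("covertAlpha")),
                   r_version = R.version.string)

  out <- list(subjects = reports, behavior = behavior,
              behavior2000 = behavior2000, hemisphere = hemisphere,
              predictor = predictor, eegEog = eegEog, peaks = peaks,
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(peaks, file.path(outDir, "peaks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(predictor))
      jsonlite::write_json(predictor[c("r", "p", "slope", "intercept", "n")],
                           file.path(outDir, "predictor.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  out
}
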