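## Task design generator: stratified trial tables and behavioral responses.

.BLOCK_SIZE <- 100L

## run expr with a temporary RNG state so generators are deterministic without
## clobbering the caller's random stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## largest-remainder allocation of n into parts proportional to p (sums to n)
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate a stratified trial table for the cued attention task
#'
#' Builds the per-trial design of one session: six cued directions, a fixed
#' fraction of validly cued targets, and a target-latency mix in which half the
#' trials have the full 2000 ms latency (the subset used for decoding), 30%
#' have 500 ms, and the remainder is uniform strictly between. All proportions
#' are enforced exactly by stratified assignment (not Bernoulli draws), then
#' the order is shuffled with the seed, so design counts are deterministic.
#'
#' @param nTrials number of trials; must be divisible by the block size (100).
#' @param validFrac fraction of validly cued trials (default 0.8).
#' @param latencyMix named numeric vector giving the fraction of trials at
#'   fixed latencies; names are latencies in ms (default
#'   \code{c("2000" = 0.5, "500" = 0.3)}). Fractions must sum to <= 1; the
#'   remainder gets an integer latency uniform strictly between 500 and
#'   2000 ms.
#' @param nDirections number of cued directions (default 6).
#' @param seed integer seed; the same seed yields an identical table.
#' @return data.frame with columns \code{trial_id}, \code{block},
#'   \code{direction}, \code{valid}, \code{target_latency_ms},
#'   \code{target_symbol}, \code{response_symbol}, \code{rt_ms},
#'   \code{correct}. Response columns are NA until [generateBehavior()] fills
#'   them.
#' @examples
#' tt <- generateTrialTable(seed = 1)
#' table(tt$valid)                      # 120 invalid, 480 valid
#' sum(tt$target_latency_ms == 2000)    # 300
#' @export
generateTrialTable <- function(nTrials = 600L, validFrac = 0.8,
                               latencyMix = c("2000" = 0.5, "500" = 0.3),
                               nDirections = 6L, seed = 1L) {
  nTrials <- as.integer(nTrials)
  if (nTrials <= 0 || nTrials %% .BLOCK_SIZE != 0L)
    stop("nTrials must be a positive multiple of the block size (",
         .BLOCK_SIZE, ")")
  if (sum(latencyMix) > 1 + 1e-12)
    stop("latencyMix fractions must sum to <= 1")
  nValid <- validFrac * nTrials
  if (abs(nValid - round(nValid)) > 1e-9)
    stop("validFrac = ", validFrac, " does not yield an integer trial count")
  nValid <- as.integer(round(nValid))
  latCounts <- latencyMix * nTrials
  if (any(abs(latCounts - round(latCounts)) > 1e-9)) {
    bad <- names(latencyMix)[which(abs(latCounts - round(latCounts)) > 1e-9)]
    stop("latencyMix fraction for ", paste(bad, collapse = ", "),
         " ms does not yield an integer trial count")
  }
  latCounts <- as.integer(round(latCounts))
  nMid <- nTrials - sum(latCounts)

  .withSeed(seed, {
    ## latency class per trial
    latency <- c(rep(as.numeric(names(latencyMix)), latCounts),
                 if (nMid > 0) sample(501:1999, nMid, replace = TRUE))
    classId <- rep(seq_len(length(latCounts) + (nMid > 0)),
                   c(latCounts, if (nMid > 0) nMid))
    ## directions round-robin within each latency class -> balanced overall
    ## and within the 2000 ms subset
    direction <- unlist(lapply(split(seq_along(latency), classId), function(i)
      rep_len(seq_len(nDirections), length(i))), use.names = FALSE)
    ## valid flags: exact count per latency class (largest remainder), spread
    ## round-robin over directions within the class
    classSizes <- as.integer(table(classId))
    validPerClass <- .apportion(nValid, classSizes)
    valid <- logical(nTrials)
    off <- 0L
    for (k in seq_along(classSizes)) {
      idx <- off + seq_len(classSizes[k])
      ord <- order(direction[idx], idx)  # interleave across directions
      valid[idx[ord][seq_len(validPerClass[k])]] <- TRUE
      off <- off + classSizes[k]
    }
    perm <- sample.int(nTrials)
    tt <- data.frame(
      trial_id = seq_len(nTrials),
      block = rep(seq_len(nTrials %/% .BLOCK_SIZE), each = .BLOCK_SIZE),
      direction = direction[perm],
      valid = valid[perm],
      target_latency_ms = latency[perm],
      target_symbol = sample(c("+", "x"), nTrials, replace = TRUE),
      response_symbol = NA_character_,
      rt_ms = NA_real_,
      correct = NA,
      stringsAsFactors = FALSE)
    tt
  })
}

#' Fill behavioral responses into a trial table
#'
#' Draws lognormal reaction times with geometric mean \code{rtGeoValid} for
#' validly cued targets and \code{rtGeoInvalid} for invalidly cued ones
#' (invalid cues slow responses because attention must be re-oriented), and a
#' correct symbol response with probability \code{pCorrect}.
#'
#' @param trials trial table from [generateTrialTable()] with empty response
#'   columns.
#' @param params a \linkS4class{SubjectParams} object.
#' @return the trial table with \code{rt_ms}, \code{response_symbol} and
#'   \code{correct} filled in.
#' @export
generateBehavior <- function(trials, params) {
  if (any(!is.na(trials$rt_ms)))
    stop("trial table already contains reaction times")
  .withSeed(params@seed + 104729, {
    n <- nrow(trials)
    geo <- ifelse(trials$valid, params@rtGeoValid, params@rtGeoInvalid)
    trials$rt_ms <- exp(log(geo) + params@rtLogSd * stats::rnorm(n))
    trials$correct <- stats::runif(n) < params@pCorrect
    other <- ifelse(trials$target_symbol == "+", "x", "+")
    trials$response_symbol <- ifelse(trials$correct, trials$target_symbol,
                                     other)
    trials
  })
}

#' Construct subject-level generative parameters
#'
#' @param subjectId subject identifier.
#' @param alphaAmp posterior resting alpha amplitude, microvolts (> 0).
#' @param effectKappa direction-dependent late alpha synchronization gain
#'   (>= 0); 0 removes all direction information from the EEG.
#' @param hemiAsym left-hemisphere asymmetry in [0, 1] for right-directed
#'   shifts.
#' @param eogConfound gain coupling ocular deflections to cue direction.
#' @param noiseSd white sensor noise, microvolts.
#' @param rtGeoValid,rtGeoInvalid geometric-mean reaction times (ms).
#' @param rtLogSd lognormal sigma of reaction times.
#' @param pCorrect probability of a correct symbol response.
#' @param seed integer seed for this subject's randomness.
#' @return a \linkS4class{SubjectParams} object.
#' @examples
#' p <- subjectParams("s01", seed = 7)
#' p
#' @export
subjectParams <- function(subjectId = "s01", alphaAmp = 6, effectKappa = 1,
                          hemiAsym = 0.3, eogConfound = 0.3, noiseSd = 3,
                          rtGeoValid = 719, rtGeoInvalid = 881,
                          rtLogSd = 0.2, pCorrect = 0.87, seed = 1L) {
  new("SubjectParams", subjectId = subjectId, alphaAmp = alphaAmp,
      effectKappa = effectKappa, hemiAsym = hemiAsym,
      eogConfound = eogConfound, noiseSd = noiseSd,
      rtGeoValid = rtGeoValid, rtGeoInvalid = rtGeoInvalid,
      rtLogSd = rtLogSd, pCorrect = pCorrect, seed = as.integer(seed))
}

#' Generate a cohort of synthetic subjects
#'
#' Draws per-subject resting alpha amplitudes from a lognormal distribution
#' and couples the direction-dependent effect strength to them,
#' \code{effectKappa = kappa0 + predictorSlope * alphaAmp + noise} truncated
#' at zero, which injects a known positive association between resting alpha
#' and downstream decoding performance.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param predictorSlope slope of the alpha -> effect coupling (default 0.45).
#' @param predictorNoise standard deviation of the coupling noise (>= 0,
#'   default 0.1).
#' @param seed integer cohort seed; subject k receives child seed
#'   \code{(seed \%\% 2e6) * 1000 + k}.
#' @param kappa0 baseline effect strength (default -0.8; with the lognormal
#'   alpha distribution this spans weak to strong decoders).
#' @param alphaMeanLog,alphaSdLog lognormal parameters of the resting alpha
#'   amplitude distribution (defaults \code{log(6)} and 0.35).
#' @param ... further arguments passed to [subjectParams()] (e.g.
#'   \code{hemiAsym}).
#' @return list of \linkS4class{SubjectParams}.
#' @export
generateCohort <- function(nSubjects = 8L, predictorSlope = 0.45,
                           predictorNoise = 0.1, seed = 1L, kappa0 = -0.8,
                           alphaMeanLog = log(6), alphaSdLog = 0.35, ...) {
  if (nSubjects < 3) stop("nSubjects must be >= 3")
  if (predictorNoise < 0) stop("predictorNoise must be >= 0")
  .withSeed(seed, {
    amp <- stats::rlnorm(nSubjects, alphaMeanLog, alphaSdLog)
    kappa <- pmax(0, kappa0 + predictorSlope * amp +
                       stats::rnorm(nSubjects, 0, predictorNoise))
    lapply(seq_len(nSubjects), function(k)
      subjectParams(subjectId = sprintf("sub%02d", k), alphaAmp = amp[k],
                    effectKappa = kappa[k],
                    seed = (as.integer(seed) %% 2000000L) * 1000L + k, ...))
  })
}
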